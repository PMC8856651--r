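{
  "comment": "ACMG/AMP 2015 evidence-combining rules. Each rule lists minimum counts of evidence items, per strength tier, in one direction. Rules are evaluated top to bottom within each direction; the first match fires. A match in both directions is a conflict and yields uncertain_significance.",
  "strengths": ["stand_alone", "very_strong", "strong", "moderate", "supporting"],
  "rules": [
    {"name": "pathogenic: 1 very-strong + >=1 strong", "verdict": "pathogenic", "direction": "pathogenic", "min": {"very_strong": 1, "strong": 1}},
    {"name": "pathogenic: 1 very-strong + >=2 moderate", "verdict": "pathogenic", "direction": "pathogenic", "min": {"very_strong": 1, "moderate": 2}},
    {"name": "pathogenic: 1 very-strong + 1 moderate + 1 supporting", "verdict": "pathogenic", "direction": "pathogenic", "min": {"very_strong": 1, "moderate": 1, "supporting": 1}},
    {"name": "pathogenic: 1 very-strong + >=2 supporting", "verdict": "pathogenic", "direction": "pathogenic", "min": {"very_strong": 1, "supporting": 2}},
    {"name": "pathogenic: >=2 strong", "verdict": "pathogenic", "direction": "pathogenic", "min": {"strong": 2}},
    {"name": "pathogenic: 1 strong + >=3 moderate", "verdict": "pathogenic", "direction": "pathogenic", "min": {"strong": 1, "moderate": 3}},
    {"name": "pathogenic: 1 strong + 2 moderate + >=2 supporting", "verdict": "pathogenic", "direction": "pathogenic", "min": {"strong": 1, "moderate": 2, "supporting": 2}},
    {"name": "pathogenic: 1 strong + 1 moderate + >=4 supporting", "verdict": "pathogenic", "direction": "pathogenic", "min": {"strong": 1, "moderate": 1, "supporting": 4}},
    {"name": "likely pathogenic: 1 very-strong + 1 moderate", "verdict": "likely_pathogenic", "direction": "pathogenic", "min": {"very_strong": 1, "moderate": 1}},
    {"name": "likely pathogenic: 1 strong + 1-2 moderate", "verdict": "likely_pathogenic", "direction": "pathogenic", "min": {"strong": 1, "moderate": 1}},
    {"name": "likely pathogenic: 1 strong + >=2 supporting", "verdict": "likely_pathogenic", "direction": "pathogenic", "min": {"strong": 1, "supporting": 2}},
    {"name": "likely pathogenic: >=3 moderate", "verdict": "likely_pathogenic", "direction": "pathogenic", "min": {"moderate": 3}},
    {"name": "likely pathogenic: 2 moderate + >=2 supporting", "verdict": "likely_pathogenic", "direction": "pathogenic", "min": {"moderate": 2, "supporting": 2}},
    {"name": "likely pathogenic: 1 moderate + >=4 supporting", "verdict": "likely_pathogenic", "direction": "pathogenic", "min": {"moderate": 1, "supporting": 4}},
    {"name": "benign: 1 stand-alone", "verdict": "benign", "direction": "benign", "min": {"stand_alone": 1}},
    {"name": "benign: >=2 strong", "verdict": "benign", "direction": "benign", "min": {"strong": 2}},
    {"name": "likely benign: 1 strong + 1 supporting", "verdict": "likely_benign", "direction": "benign", "min": {"strong": 1, "supporting": 1}},
    {"name": "likely benign: >=2 supporting", "verdict": "likely_benign", "direction": "benign", "min": {"supporting": 2}}
  ]
}
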