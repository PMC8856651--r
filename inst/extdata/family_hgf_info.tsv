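id	generation	alive
I-1	1	FALSE
I-2	1	FALSE
II-1	2	TRUE
II-2	2	TRUE
II-3	2	TRUE
II-4	2	TRUE
II-5	2	TRUE
II-6	2	TRUE
II-7	2	TRUE
II-8	2	TRUE
II-9	2	TRUE
III-1	3	TRUE
III-2	3	TRUE
III-3	3	TRUE
III-4	3	TRUE
III-5	3	TRUE
III-6	3	TRUE
III-7	3	TRUE
III-8	3	TRUE
III-9	3	TRUE
IV-1	4	TRUE
IV-2	4	TRUE
IV-3	4	TRUE
IV-4	4	TRUE
IV-5	4	TRUE
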