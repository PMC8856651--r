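# Default direction/strength of the standard ACMG/AMP criterion codes.
.acmg_defaults <- local({
  codes <- c(PVS1 = "very_strong",
             PS1 = "strong", PS2 = "strong", PS3 = "strong", PS4 = "strong",
             PM1 = "moderate", PM2 = "moderate", PM3 = "moderate",
             PM4 = "moderate", PM5 = "moderate", PM6 = "moderate",
             PP1 = "supporting", PP2 = "supporting", PP3 = "supporting",
             PP4 = "supporting", PP5 = "supporting",
             BA1 = "stand_alone",
             BS1 = "strong", BS2 = "strong", BS3 = "strong", BS4 = "strong",
             BP1 = "supporting", BP2 = "supporting", BP3 = "supporting",
             BP4 = "supporting", BP5 = "supporting", BP6 = "supporting",
             BP7 = "supporting")
  data.frame(code = names(codes), strength = unname(codes),
             direction = ifelse(substr(names(codes), 1, 1) == "P",
                                "pathogenic", "benign"),
             stringsAsFactors = FALSE)
})

#' Build an ACMG evidence item
#'
#' Standard codes (PVS1, PS1-4, PM1-6, PP1-5, BA1, BS1-4, BP1-7) carry their
#' guideline default strength and direction; strength may be modified (e.g.
#' PP1 applied at strong on linkage evidence). Non-standard codes must
#' declare both strength and direction.
#'
#' @param code criterion code string.
#' @param strength one of `stand_alone`, `very_strong`, `strong`,
#'   `moderate`, `supporting`; default the code's guideline strength.
#' @param direction `"pathogenic"` or `"benign"`; default per code.
#' @param note free-text provenance note.
#' @return one-row data frame (`code`, `strength`, `direction`, `note`,
#'   `modified`).
#' @export
evidence_item <- function(code, strength = NULL, direction = NULL, note = "") {
  i <- match(code, .acmg_defaults$code)
  if (is.na(i) && (is.null(strength) || is.null(direction))) {
    stop("evidence_item(): unknown code '", code,
         "' requires explicit strength and direction")
  }
  default_strength <- if (!is.na(i)) .acmg_defaults$strength[i] else NA
  if (is.null(strength)) strength <- default_strength
  if (is.null(direction)) direction <- .acmg_defaults$direction[i]
  strengths <- c("stand_alone", "very_strong", "strong", "moderate", "supporting")
  if (!strength %in% strengths) stop("evidence_item(): bad strength ", strength)
  if (!direction %in% c("pathogenic", "benign")) {
    stop("evidence_item(): bad direction ", direction)
  }
  data.frame(code = code, strength = strength, direction = direction,
             note = note,
             modified = !is.na(default_strength) && strength != default_strength,
             stringsAsFactors = FALSE)
}

#' Map a co-segregation LOD score to a PP1 evidence strength
#'
#' PP1 (co-segregation with disease in multiple affected family members) is
#' strength-scalable. Defaults: supporting at LOD >= 0.6, moderate at
#' LOD >= 1.5, and strong strictly above LOD 3 (the strong cutoff is the
#' anchored one; lower tiers follow common co-segregation practice). Returns
#' `NULL` below the supporting threshold.
#'
#' @param lod_max maximized two-point LOD.
#' @param thresholds named numeric vector, minimum LOD per strength, must be
#'   increasing from supporting to strong. The strong tier is applied as a
#'   strict inequality, lower tiers as >=.
#' @return an evidence item (PP1 at the earned strength) or `NULL`.
#' @export
pp1_strength <- function(lod_max,
                         thresholds = c(supporting = 0.6, moderate = 1.5,
                                        strong = 3.0)) {
  need <- c("supporting", "moderate", "strong")
  if (!all(need %in% names(thresholds))) {
    stop("pp1_strength(): thresholds must name supporting, moderate, strong")
  }
  th <- thresholds[need]
  if (is.unsorted(th, strictly = TRUE)) {
    stop("pp1_strength(): thresholds must be strictly increasing with strength")
  }
  note <- sprintf("co-segregation LOD = %.4g", lod_max)
  if (lod_max > th[["strong"]]) {
    evidence_item("PP1", strength = "strong", note = note)
  } else if (lod_max >= th[["moderate"]]) {
    evidence_item("PP1", strength = "moderate", note = note)
  } else if (lod_max >= th[["supporting"]]) {
    evidence_item("PP1", strength = "supporting", note = note)
  } else {
    NULL
  }
}

#' Load the ACMG combining-rule table
#' @param path JSON rule-table path; default the table shipped with the
#'   package.
#' @return list with `strengths` and `rules`.
#' @export
acmg_rules <- function(path = system.file("extdata", "acmg_rules.json",
                                          package = "famseg")) {
  jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
}

.first_firing_rule <- function(rules, direction, counts) {
  for (rule in rules) {
    if (rule$direction != direction) next
    need <- unlist(rule$min)
    if (all(counts[names(need)] >= need)) return(rule)
  }
  NULL
}

#' Combine ACMG evidence items into a five-tier classification
#'
#' Applies the guideline combining rules (shipped as an editable JSON table)
#' over counts of evidence items per (direction, strength). The first rule
#' whose minimum counts are met fires, per direction; criteria met in both
#' directions are a conflict and yield `uncertain_significance`, as does no
#' rule firing at all.
#'
#' @param evidence data frame of evidence items ([evidence_item()] rows
#'   bound together), or a list of such rows.
#' @param rules rule table from [acmg_rules()].
#' @return list of class `famseg_classification`: `verdict`, `fired_rule`,
#'   `evidence`.
#' @export
combine_evidence <- function(evidence, rules = acmg_rules()) {
  if (is.list(evidence) && !is.data.frame(evidence)) {
    evidence <- do.call(rbind, evidence)
  }
  if (is.null(evidence) || !nrow(evidence)) {
    return(structure(list(verdict = "uncertain_significance",
                          fired_rule = "no evidence", evidence = evidence),
                     class = "famseg_classification"))
  }
  strengths <- rules$strengths
  counts <- function(dir) {
    sub <- evidence[evidence$direction == dir, , drop = FALSE]
    stats::setNames(vapply(strengths, function(s) sum(sub$strength == s),
                           numeric(1)), strengths)
  }
  rp <- .first_firing_rule(rules$rules, "pathogenic", counts("pathogenic"))
  rb <- .first_firing_rule(rules$rules, "benign", counts("benign"))
  if (!is.null(rp) && !is.null(rb)) {
    verdict <- "uncertain_significance"
    fired <- paste0("conflict: [", rp$name, "] vs [", rb$name, "]")
  } else if (!is.null(rp)) {
    verdict <- rp$verdict; fired <- rp$name
  } else if (!is.null(rb)) {
    verdict <- rb$verdict; fired <- rb$name
  } else {
    verdict <- "uncertain_significance"; fired <- "no combining rule met"
  }
  structure(list(verdict = verdict, fired_rule = fired, evidence = evidence),
            class = "famseg_classification")
}

#' @export
print.famseg_classification <- function(x, ...) {
  ev <- if (is.null(x$evidence) || !nrow(x$evidence)) "none" else
    paste(sprintf("%s(%s)", x$evidence$code, x$evidence$strength),
          collapse = ", ")
  cat(sprintf("<famseg_classification>: %s [rule: %s] evidence: %s\n",
              x$verdict, x$fired_rule, ev))
  invisible(x)
}
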