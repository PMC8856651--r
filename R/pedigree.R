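#' Pedigree construction and validation
#'
#' A `famseg_pedigree` stores one family as a data frame of individuals with
#' parent links, sex, affection status, vital status and a genotyped flag.
#' Founders (including married-in spouses) have both parent ids `NA`.
#'
#' @param individuals data frame with columns `id`, `father_id`, `mother_id`,
#'   `sex` (`"male"`, `"female"`, `"unknown"`), `affected` (`"affected"`,
#'   `"unaffected"`, `"unknown"`), `alive` (logical), `genotyped` (logical).
#'   Optionally `generation` (integer).
#' @param name family name.
#' @return object of class `famseg_pedigree`.
#' @export
pedigree <- function(individuals, name = "family") {
  required <- c("id", "father_id", "mother_id", "sex", "affected",
                "alive", "genotyped")
  missing_cols <- setdiff(required, names(individuals))
  if (length(missing_cols)) {
    stop("pedigree(): missing columns: ", paste(missing_cols, collapse = ", "))
  }
  individuals$id <- as.character(individuals$id)
  individuals$father_id <- as.character(individuals$father_id)
  individuals$mother_id <- as.character(individuals$mother_id)
  ped <- structure(list(individuals = individuals, name = name),
                   class = "famseg_pedigree")
  validate_pedigree(ped)
  ped
}

#' @export
print.famseg_pedigree <- function(x, ...) {
  ind <- x$individuals
  cat(sprintf("<famseg_pedigree '%s'>: %d individuals (%d affected, %d genotyped, %d founders)\n",
              x$name, nrow(ind), sum(ind$affected == "affected"),
              sum(ind$genotyped), sum(is.na(ind$father_id) & is.na(ind$mother_id))))
  invisible(x)
}

#' Validate pedigree structural invariants
#'
#' Checks id uniqueness, parent-link closure (both parents present or both
#' absent), sex consistency of parents, acyclicity, and presence of at least
#' one founder.
#'
#' @param ped a `famseg_pedigree`.
#' @return `ped`, invisibly; stops on violation.
#' @export
validate_pedigree <- function(ped) {
  ind <- ped$individuals
  if (anyDuplicated(ind$id)) {
    stop("pedigree invariant violated: duplicate individual ids: ",
         paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "))
  }
  half <- xor(is.na(ind$father_id), is.na(ind$mother_id))
  if (any(half)) {
    stop("pedigree invariant violated: individuals with exactly one parent: ",
         paste(ind$id[half], collapse = ", "))
  }
  nonf <- !is.na(ind$father_id)
  bad_ref <- nonf & (!(ind$father_id %in% ind$id) | !(ind$mother_id %in% ind$id))
  if (any(bad_ref)) {
    stop("pedigree structural error: unknown parent id for: ",
         paste(ind$id[bad_ref], collapse = ", "))
  }
  if (!any(!nonf)) stop("pedigree invariant violated: no founders")
  sex_of <- stats::setNames(ind$sex, ind$id)
  fsex <- sex_of[ind$father_id[nonf]]
  msex <- sex_of[ind$mother_id[nonf]]
  if (any(fsex == "female") || any(msex == "male")) {
    stop("pedigree invariant violated: parent sex inconsistent with role")
  }
  # acyclicity: iteratively peel individuals whose parents are already peeled
  done <- stats::setNames(is.na(ind$father_id), ind$id)
  repeat {
    newly <- !done & done[ind$father_id] & done[ind$mother_id]
    newly[is.na(newly)] <- FALSE
    if (!any(newly)) break
    done[names(newly)[newly]] <- TRUE
  }
  if (!all(done)) {
    stop("pedigree invariant violated: cyclic parent links involving: ",
         paste(names(done)[!done], collapse = ", "))
  }
  invisible(ped)
}

#' Read a pedigree from a 6-column PED file
#'
#' Standard whitespace-delimited PED dialect: family id, individual id,
#' father id, mother id, sex (1 = male, 2 = female, 0 = unknown), phenotype
#' (2 = affected, 1 = unaffected, 0 or -9 = unknown). `0` denotes a missing
#' parent. Lines starting with `#` are comments. Vital status and generation
#' can be carried in a sidecar TSV with columns `id`, `generation`, `alive`;
#' without a sidecar all individuals are taken as alive. Individuals are
#' flagged `genotyped` iff alive (override via the sidecar's optional
#' `genotyped` column).
#'
#' @param path PED file path.
#' @param sidecar optional TSV path.
#' @return a `famseg_pedigree`.
#' @export
read_ped <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("read_ped(): file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines_kept <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(trimws(lines_kept), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 6)) {
    stop(sprintf("read_ped(): malformed row at line %d: expected >= 6 columns, got %d",
                 lineno[which(nf < 6)[1]], nf[which(nf < 6)[1]]))
  }
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  sex <- c("0" = "unknown", "1" = "male", "2" = "female")[m[, 5]]
  sex[is.na(sex)] <- "unknown"
  aff <- rep("unknown", nrow(m))
  aff[m[, 6] == "2"] <- "affected"
  aff[m[, 6] == "1"] <- "unaffected"
  ind <- data.frame(
    id = m[, 2],
    father_id = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother_id = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = unname(sex),
    affected = aff,
    alive = TRUE,
    genotyped = TRUE,
    stringsAsFactors = FALSE
  )
  if (!is.null(sidecar)) {
    sc <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
    sc$id <- as.character(sc$id)
    i <- match(ind$id, sc$id)
    if ("alive" %in% names(sc)) {
      ind$alive <- ifelse(is.na(i), TRUE, as.logical(sc$alive[i]))
    }
    ind$genotyped <- if ("genotyped" %in% names(sc)) {
      ifelse(is.na(i), ind$alive, as.logical(sc$genotyped[i]))
    } else ind$alive
    if ("generation" %in% names(sc)) ind$generation <- sc$generation[i]
  }
  pedigree(ind, name = m[1, 1])
}

#' Write a pedigree in the canonical 6-column PED dialect
#'
#' @param ped a `famseg_pedigree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  ind <- ped$individuals
  sex <- c(male = "1", female = "2", unknown = "0")[ind$sex]
  phe <- c(affected = "2", unaffected = "1", unknown = "0")[ind$affected]
  rows <- paste(ped$name, ind$id,
                ifelse(is.na(ind$father_id), "0", ind$father_id),
                ifelse(is.na(ind$mother_id), "0", ind$mother_id),
                sex, phe, sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Carrier map from genotypes and affection under full penetrance
#'
#' Builds a named logical carrier-status vector (`TRUE` = carries the
#' variant, `NA` = unknown) over all pedigree members. Genotyped members take
#' status from `genotype_calls` when given (het or hom-alt means carrier),
#' otherwise from affection. Ungenotyped members get status from affection
#' when `affection_proxy = TRUE` (full penetrance makes affection a perfect
#' proxy; used for deceased founders), otherwise `NA`, then obligate-carrier
#' closure is applied.
#'
#' @param ped a `famseg_pedigree`.
#' @param genotype_calls optional named integer vector (0 = hom-ref, 1 = het,
#'   2 = hom-alt, NA = missing) over genotyped ids.
#' @param affection_proxy use affection for ungenotyped members (default TRUE).
#' @return named logical vector over all ids.
#' @export
resolve_carriers <- function(ped, genotype_calls = NULL, affection_proxy = TRUE) {
  ind <- ped$individuals
  carriers <- stats::setNames(rep(NA, nrow(ind)), ind$id)
  gt_ids <- ind$id[ind$genotyped]
  if (!is.null(genotype_calls)) {
    known <- intersect(gt_ids, names(genotype_calls))
    carriers[known] <- genotype_calls[known] >= 1
  } else {
    carriers[gt_ids] <- ind$affected[ind$genotyped] == "affected"
  }
  if (affection_proxy) {
    ung <- ind$id[!ind$genotyped & ind$affected != "unknown"]
    carriers[ung] <- ind$affected[match(ung, ind$id)] == "affected"
  }
  obl <- obligate_carriers(ped, carriers)
  carriers[obl] <- TRUE
  carriers
}

#' Infer obligate carriers by Mendelian closure
#'
#' An ungenotyped individual with at least one carrier child whose other
#' parent is a known non-carrier must itself carry the variant (the variant
#' is rare; it cannot arise de novo in several children). Applied
#' transitively until a fixed point under the fully penetrant dominant model.
#'
#' @param ped a `famseg_pedigree`.
#' @param carriers named logical vector of carrier statuses (`NA` unknown);
#'   must cover every genotyped individual.
#' @return character vector of ids newly inferred as carriers.
#' @export
obligate_carriers <- function(ped, carriers) {
  ind <- ped$individuals
  gt_ids <- ind$id[ind$genotyped]
  if (!all(gt_ids %in% names(carriers)) ||
      any(is.na(carriers[gt_ids]))) {
    stop("obligate_carriers(): carrier status required for all genotyped individuals")
  }
  status <- stats::setNames(rep(NA, nrow(ind)), ind$id)
  status[names(carriers)] <- carriers
  inferred <- character(0)
  candidates <- ind$id[!ind$genotyped]
  repeat {
    changed <- FALSE
    for (u in candidates) {
      if (isTRUE(status[[u]])) next
      kids <- ind[!is.na(ind$father_id) &
                    (ind$father_id == u | ind$mother_id == u), , drop = FALSE]
      if (!nrow(kids)) next
      co <- ifelse(kids$father_id == u, kids$mother_id, kids$father_id)
      forced <- !is.na(status[kids$id]) & status[kids$id] &
        !is.na(status[co]) & !status[co]
      if (any(forced)) {
        if (isFALSE(status[[u]])) {
          stop("obligate_carriers(): inconsistency: ", u,
               " is a stated non-carrier but is forced to be a carrier by ",
               paste(kids$id[forced], collapse = ", "))
        }
        status[u] <- TRUE
        inferred <- c(inferred, u)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  inferred
}

#' Enumerate informative meioses under the dominant model
#'
#' One informative meiosis per genotyped child with exactly one carrier
#' parent (genotyped or obligate): the transmission of the variant through
#' that parent is then phase-known and scorable. Children of two carrier
#' parents are excluded (transmission not attributable to either parent),
#' as are children whose carrier parent's co-parent has unknown status.
#'
#' @param ped a `famseg_pedigree`.
#' @param carriers named logical carrier map covering genotyped individuals
#'   (obligate carriers already resolved, e.g. via [resolve_carriers()]).
#' @return a `famseg_meioses` list: `meioses` (data frame `parent_id`,
#'   `child_id`), `n_informative`, `excluded` (data frame with `reason`).
#' @export
informative_meioses <- function(ped, carriers) {
  ind <- ped$individuals
  status <- stats::setNames(rep(NA, nrow(ind)), ind$id)
  status[names(carriers)] <- carriers
  kids <- ind[ind$genotyped & !is.na(ind$father_id), , drop = FALSE]
  meioses <- data.frame(parent_id = character(0), child_id = character(0),
                        stringsAsFactors = FALSE)
  excluded <- data.frame(parent_id = character(0), child_id = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(kids))) {
    f <- status[kids$father_id[i]]
    m <- status[kids$mother_id[i]]
    if (isTRUE(f) && isTRUE(m)) {
      excluded <- rbind(excluded, data.frame(
        parent_id = NA_character_, child_id = kids$id[i],
        reason = "both parents carriers: phase unresolvable"))
    } else if (isTRUE(f) || isTRUE(m)) {
      carrier_parent <- if (isTRUE(f)) kids$father_id[i] else kids$mother_id[i]
      other <- if (isTRUE(f)) m else f
      if (is.na(other)) {
        excluded <- rbind(excluded, data.frame(
          parent_id = carrier_parent, child_id = kids$id[i],
          reason = "co-parent carrier status unknown"))
      } else {
        meioses <- rbind(meioses, data.frame(
          parent_id = carrier_parent, child_id = kids$id[i]))
      }
    }
  }
  structure(list(meioses = meioses, n_informative = nrow(meioses),
                 excluded = excluded),
            class = "famseg_meioses")
}

#' @export
print.famseg_meioses <- function(x, ...) {
  cat(sprintf("<famseg_meioses>: %d informative, %d excluded\n",
              x$n_informative, nrow(x$excluded)))
  invisible(x)
}
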