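# Hybrid audiogram / phecode phenotype derivation.
#
# The study phenotype is "degree HL", an ordinal 0-4 severity scale.
# Individuals with audiograms are graded from the air-conduction
# pure-tone average (PTA) of the worse ear; individuals without
# audiograms are kept as degree 0 only if they are phecode-defined
# controls (zero billing instances of the hearing-loss phecode), and are
# excluded otherwise.

PTA_FREQS <- c(500, 1000, 2000)

#' Pure-tone average for one ear at one exam
#'
#' Arithmetic mean of the air-conduction (or bone-conduction) hearing
#' thresholds at 500, 1000 and 2000 Hz.
#'
#' @param frequency_hz Numeric vector of test frequencies in Hz.
#' @param threshold_db Numeric vector of hearing thresholds in dB HL,
#'   parallel to `frequency_hz`.
#' @return The PTA in dB HL (length-1 numeric).
#' @examples
#' compute_pta(c(500, 1000, 2000), c(10, 20, 30))  # 20
#' @export
compute_pta <- function(frequency_hz, threshold_db) {
  if (length(frequency_hz) != length(threshold_db))
    stop_input("frequency and threshold vectors must have equal length")
  idx <- match(PTA_FREQS, frequency_hz)
  if (anyNA(idx) || anyNA(threshold_db[idx]))
    stop_input("PTA requires thresholds at 500, 1000 and 2000 Hz")
  mean(threshold_db[idx])
}

#' Worse-ear air-conduction PTA for one individual
#'
#' Selects one exam (most recent by default, or the worst-ever ear), then
#' returns the larger air-conduction PTA across ears with complete
#' 500/1000/2000 Hz measurements. If only one ear is complete at the
#' selected exam, that ear's PTA is returned.
#'
#' @param audiograms Data frame with columns `date`, `ear`, `conduction`,
#'   `frequency_hz`, `threshold_db` for a single individual.
#' @param exam Exam-selection rule when several exams exist:
#'   `"latest"` (default) uses the most recent exam date; `"worst"` uses
#'   the maximum PTA over all exams and ears.
#' @return Worse-ear air-conduction PTA in dB HL.
#' @export
worse_ear_pta <- function(audiograms, exam = c("latest", "worst")) {
  exam <- match.arg(exam)
  air <- audiograms[audiograms$conduction == "air", , drop = FALSE]
  if (nrow(air) == 0L) stop_input("no air-conduction records")
  ptas <- ear_exam_ptas(air)
  if (nrow(ptas) == 0L)
    stop_input("no ear with complete 500/1000/2000 Hz air conduction")
  if (exam == "latest") {
    ptas <- ptas[ptas$date == max(ptas$date), , drop = FALSE]
  }
  max(ptas$pta)
}

# per (date, ear) PTA over complete ears only
ear_exam_ptas <- function(air) {
  keys <- unique(air[c("date", "ear")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- air[air$date == keys$date[i] & air$ear == keys$ear[i], ]
    idx <- match(PTA_FREQS, sub$frequency_hz)
    if (anyNA(idx) || anyNA(sub$threshold_db[idx])) return(NULL)
    data.frame(date = keys$date[i], ear = keys$ear[i],
               pta = mean(sub$threshold_db[idx]))
  })
  do.call(rbind, c(out[!vapply(out, is.null, TRUE)],
                   list(make.row.names = FALSE)))
}

#' Map a PTA to degree of hearing loss (0-4)
#'
#' Bins: PTA <= 15 -> 0 (none), (15, 25] -> 1 (mild), (25, 40] -> 2
#' (moderate), (40, 55] -> 3 (severe), > 55 -> 4 (profound). The
#' published bins are integer ranges (0-15, 16-25, 26-40, 41-55, 56+);
#' since a PTA is a mean and can be fractional, boundaries are treated as
#' half-open intervals with the boundary in the lower degree.
#'
#' @param pta Numeric vector of PTA values in dB HL.
#' @return Integer vector of degrees in `0:4`.
#' @examples
#' pta_to_degree(c(-5, 15, 20, 40.5, 56))  # 0 0 1 3 4
#' @export
pta_to_degree <- function(pta) {
  if (!is.numeric(pta) || any(!is.finite(pta)))
    stop_input("'pta' must be finite numeric")
  as.integer(cut(pta, c(-Inf, 15, 25, 40, 55, Inf), labels = FALSE)) - 1L
}

#' Phecode case/control status from instance counts
#'
#' Two or more billing instances of the target phecode make a case, zero
#' instances a control, and exactly one instance is indeterminate (NA).
#'
#' @param count Nonnegative integer vector of phecode instance counts.
#' @return Character vector in `c("case", "control", NA)`.
#' @export
phecode_status <- function(count) {
  if (any(!is.finite(count)) || any(count < 0))
    stop_input("'count' must be nonnegative")
  ifelse(count >= 2, "case", ifelse(count == 0, "control", NA_character_))
}

#' Assign the hybrid degree-HL phenotype
#'
#' Individuals with an audiogram receive the degree implied by their
#' worse-ear air-conduction PTA, regardless of phecode status.
#' Individuals without an audiogram are included as degree 0 when they
#' are phecode controls, and excluded (with a reason) when they are
#' phecode cases or indeterminate.
#'
#' @param audiograms Audiogram table (`individual_id`, `date`, `ear`,
#'   `conduction`, `frequency_hz`, `threshold_db`); may have zero rows.
#' @param phecodes Data frame with one row per billing instance
#'   (`individual_id`, ...), or a pre-counted table with columns
#'   `individual_id` and `n_instances`.
#' @param individual_ids Character vector of all cohort individuals
#'   (defines the output universe). Defaults to ids seen in either input.
#' @param exam Exam-selection rule passed to [worse_ear_pta()].
#' @return A `data.frame` with one row per individual: `individual_id`,
#'   `degree_hl`, `pta`, `source` ("audiogram"/"phecode-control"),
#'   `included`, `exclusion_reason`.
#' @export
assign_phenotype <- function(audiograms, phecodes, individual_ids = NULL,
                             exam = "latest") {
  counts <- phecode_counts(phecodes)
  if (is.null(individual_ids))
    individual_ids <- union(unique(audiograms$individual_id),
                            counts$individual_id)
  if (anyDuplicated(individual_ids))
    stop_input("duplicate individual ids")
  n <- length(individual_ids)
  status <- phecode_status(counts$n_instances[
    match(individual_ids, counts$individual_id)] |> replace_na(0))

  pta <- rep(NA_real_, n)
  if (nrow(audiograms)) {
    per_ind <- split(audiograms,
                     factor(audiograms$individual_id, individual_ids))
    got <- vapply(per_ind, nrow, 0L) > 0
    pta[got] <- vapply(per_ind[got], function(sub) {
      tryCatch(worse_ear_pta(sub, exam = exam),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  has_pta <- !is.na(pta)

  degree <- rep(NA_integer_, n)
  source <- rep(NA_character_, n)
  included <- rep(FALSE, n)
  reason <- rep(NA_character_, n)

  degree[has_pta] <- pta_to_degree(pta[has_pta])
  source[has_pta] <- "audiogram"
  included[has_pta] <- TRUE

  ctrl <- !has_pta & !is.na(status) & status == "control"
  degree[ctrl] <- 0L
  source[ctrl] <- "phecode-control"
  included[ctrl] <- TRUE

  excl <- !included
  reason[excl & !is.na(status) & status == "case"] <- "phecode-case-no-audiogram"
  reason[excl & is.na(reason)] <- "phecode-na-no-audiogram"

  data.frame(individual_id = individual_ids, degree_hl = degree, pta = pta,
             source = source, included = included, exclusion_reason = reason,
             stringsAsFactors = FALSE)
}

replace_na <- function(x, value) { x[is.na(x)] <- value; x }

phecode_counts <- function(phecodes) {
  if ("n_instances" %in% names(phecodes)) {
    phecodes[c("individual_id", "n_instances")]
  } else {
    tab <- table(phecodes$individual_id)
    data.frame(individual_id = names(tab),
               n_instances = as.integer(tab), stringsAsFactors = FALSE)
  }
}

#' Binary case/control labels from the degree-HL phenotype
#'
#' Cases are included individuals with degree HL 2-4; controls are
#' included individuals with degree HL 0-1 (including phecode-derived
#' degree 0). Excluded individuals get no label.
#'
#' @param phenotypes Output of [assign_phenotype()].
#' @return Character vector parallel to `phenotypes` rows, `"case"`,
#'   `"control"` or `NA`.
#' @export
binarize_case_control <- function(phenotypes) {
  out <- rep(NA_character_, nrow(phenotypes))
  inc <- phenotypes$included
  out[inc & phenotypes$degree_hl >= 2] <- "case"
  out[inc & phenotypes$degree_hl <= 1] <- "control"
  out
}

#' Cross-tabulate phecode status against audiogram positivity
#'
#' Among individuals with audiograms, tabulates phecode status (case /
#' control / NA) against audiogram-defined hearing loss (worse-ear
#' air-conduction PTA strictly greater than `pta_cutoff`), and reports
#' the per-status audiogram-positive rates. This is the misclassification
#' cross-check of EHR labels against audiometry.
#'
#' @param phenotypes Output of [assign_phenotype()] (uses rows with a PTA).
#' @param phecodes Phecode instance table or pre-counted table.
#' @param pta_cutoff Positivity cutoff in dB HL (default 25, i.e. >25).
#' @return A list with `counts` (status x positivity table) and `rates`
#'   (named vector: audiogram-positive proportion among phecode cases and
#'   controls).
#' @export
misclassification_rates <- function(phenotypes, phecodes, pta_cutoff = 25) {
  counts <- phecode_counts(phecodes)
  sub <- phenotypes[!is.na(phenotypes$pta), ]
  status <- phecode_status(replace_na(
    counts$n_instances[match(sub$individual_id, counts$individual_id)], 0))
  pos <- sub$pta > pta_cutoff
  tab <- table(status = factor(status, c("case", "control")),
               audiogram_positive = pos, useNA = "ifany")
  rate <- function(s) {
    k <- status %in% s
    if (!any(k)) return(NA_real_)
    mean(pos[k])
  }
  list(counts = tab,
       rates = c(case = rate("case"), control = rate("control")))
}
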