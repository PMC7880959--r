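check_pair <- function(a, b) {
  if (length(a) != length(b))
    stop("label sequences have different lengths (", length(a), " vs ",
         length(b), ")")
}

#' Sample-level misclassification proportion
#'
#' Proportion of samples for which two per-sample labelings disagree, over
#' the universe of samples that either labeling assigns to one of the
#' included categories.  Sub-labels are collapsed first
#' ([collapse_labels()]), so high- and low-velocity PSOs count as one PSO
#' category and chunk-boundary/intra-chunk saccades as one saccade category.
#' Samples where only one labeling assigns an included label are part of the
#' universe and count as disagreements.
#'
#' @param a,b Character vectors of per-sample labels, equal length.
#' @param include_labels Categories defining the comparison universe.
#' @return Proportion in \[0, 1\].
#' @examples
#' misclassification(c("FIXA", "FIXA", "SACC", "SACC"),
#'                   c("FIXA", "SACC", "SACC", "PURS"))
#' @export
misclassification <- function(a, b,
                              include_labels = c("FIXA", "SACC", "PSO",
                                                 "PURS")) {
  check_pair(a, b)
  a <- collapse_labels(as.character(a))
  b <- collapse_labels(as.character(b))
  sel <- a %in% include_labels | b %in% include_labels
  if (!any(sel))
    stop("no samples carry an included label; misclassification undefined")
  mean(a[sel] != b[sel])
}

#' Sample-level Jaccard index for one category
#'
#' Ratio of the number of samples both labelings assign to `category` to the
#' number of samples either assigns to it.  Sub-labels are collapsed first.
#' When the category is absent from both labelings the index is 1 by
#' convention (with a warning).
#'
#' @inheritParams misclassification
#' @param category The label whose sample sets are compared.
#' @return Index in \[0, 1\].
#' @export
jaccard <- function(a, b, category) {
  check_pair(a, b)
  a <- collapse_labels(as.character(a)) == category
  b <- collapse_labels(as.character(b)) == category
  union <- sum(a | b)
  if (union == 0L) {
    warning("category '", category,
            "' absent from both sequences; Jaccard index 1 by convention")
    return(1)
  }
  sum(a & b) / union
}

#' Cohen's kappa between two per-sample labelings
#'
#' Chance-corrected sample-by-sample agreement,
#' `K = (P_o - P_c) / (1 - P_c)`, where `P_o` is the observed proportion of
#' agreement and `P_c` the chance agreement computed from the two sequences'
#' marginal label frequencies.  `K = 1` indicates perfect agreement and
#' `K = 0` chance-level agreement.  With `category` set, both sequences are
#' first binarized into category vs. rest (the per-event-type variant used
#' when comparing against human coders).  Sub-labels are collapsed first.
#'
#' @inheritParams misclassification
#' @param category Optional label for a binary (one-vs-rest) kappa.
#' @return Kappa in \[-1, 1\].
#' @examples
#' cohens_kappa(c("F", "F", "S", "S"), c("F", "S", "F", "S"))  # 0
#' @export
cohens_kappa <- function(a, b, category = NULL) {
  check_pair(a, b)
  a <- collapse_labels(as.character(a))
  b <- collapse_labels(as.character(b))
  if (!is.null(category)) {
    a <- ifelse(a == category, category, "rest")
    b <- ifelse(b == category, category, "rest")
  }
  po <- mean(a == b)
  vocab <- union(unique(a), unique(b))
  pa <- vapply(vocab, function(l) mean(a == l), numeric(1))
  pb <- vapply(vocab, function(l) mean(b == l), numeric(1))
  pc <- sum(pa * pb)
  if (pc >= 1)
    stop("both sequences are constant and identical; kappa is undefined")
  (po - pc) / (1 - pc)
}

#' Full sample-level agreement report
#'
#' Convenience wrapper computing the misclassification proportion, Cohen's
#' kappa, and the pairwise Jaccard confusion matrix (cell `(i, j)` compares
#' the samples labeled `i` by `a` with those labeled `j` by `b`) over the
#' included categories.
#'
#' @inheritParams misclassification
#' @return A list of class `agreement_report` with elements
#'   `misclassification`, `kappa`, and `confusion` (Jaccard matrix).
#' @export
agreement_report <- function(a, b,
                             include_labels = c("FIXA", "SACC", "PSO",
                                                "PURS")) {
  check_pair(a, b)
  a <- collapse_labels(as.character(a))
  b <- collapse_labels(as.character(b))
  conf <- matrix(NA_real_, length(include_labels), length(include_labels),
                 dimnames = list(a = include_labels, b = include_labels))
  for (i in include_labels) for (j in include_labels) {
    ai <- a == i; bj <- b == j
    u <- sum(ai | bj)
    conf[i, j] <- if (u == 0L) NA_real_ else sum(ai & bj) / u
  }
  structure(
    list(misclassification = misclassification(a, b, include_labels),
         kappa = cohens_kappa(a, b),
         confusion = conf),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> misclassification=%.4f kappa=%.4f\n",
              x$misclassification, x$kappa))
  cat("Jaccard confusion (rows: a, cols: b):\n")
  print(round(x$confusion, 3))
  invisible(x)
}

event_type_stats <- function(events, label) {
  if (!is.null(events$duration)) d <- events$duration
  else d <- events$offset_time - events$onset_time
  d <- d[collapse_labels(as.character(events$label)) == label]
  c(mean = if (length(d)) mean(d) else NA_real_,
    sd = if (length(d) > 1L) stats::sd(d) else NA_real_,
    n = length(d))
}

#' Duration-statistics RMSD against two reference raters
#'
#' For each event type, summarizes an event list by the 3-vector (mean event
#' duration, SD of durations, number of events) and scores a candidate by
#' the root-mean-square deviation of its normalized summary from the average
#' of the two reference raters' summaries.  Each characteristic is
#' normalized by its maximum across the compared entities (candidate and
#' both raters), so the score is scale-free; 0 means the candidate equals
#' the rater average.  Characteristics undefined for an empty or
#' single-event list (with a warning) are dropped from the mean.
#'
#' @param candidate_events,rater1_events,rater2_events Event tables (from
#'   [classify_recording()] or [read_events()]) with `label` and either a
#'   `duration` column or `onset_time`/`offset_time` columns.
#' @param labels Event types to score (sub-labels are collapsed).
#' @return Named numeric vector of RMSD scores, one per event type.
#' @export
duration_stats_rmsd <- function(candidate_events, rater1_events,
                                rater2_events,
                                labels = c("FIXA", "SACC", "PSO", "PURS")) {
  out <- vapply(labels, function(lab) {
    sc <- event_type_stats(candidate_events, lab)
    s1 <- event_type_stats(rater1_events, lab)
    s2 <- event_type_stats(rater2_events, lab)
    avg <- (s1 + s2) / 2
    norm <- pmax(abs(sc), abs(s1), abs(s2))
    dev <- (sc - avg) / norm
    dev[!is.finite(dev) & is.finite(sc) & is.finite(avg) & norm == 0] <- 0
    ok <- is.finite(dev)
    if (!all(ok))
      warning("event type '", lab, "': ", sum(!ok),
              " undefined characteristic(s) dropped from the RMSD")
    if (!any(ok)) return(NA_real_)
    sqrt(mean(dev[ok]^2))
  }, numeric(1))
  names(out) <- labels
  out
}
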