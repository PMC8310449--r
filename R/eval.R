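# Span-exact NER evaluation: a predicted mention counts as a true positive
# iff its (start, end, label) triple exactly matches a gold mention in the
# same record (strict CoNLL convention). Metrics are on the 0-100 scale.

#' Harmonic-mean F1 on the 0-100 scale
#'
#' @param p,r Precision and recall percentages.
#' @return F1 percentage; 0 when both inputs are 0.
#' @export
#' @examples
#' f1_score(86.57, 87.04)   # 86.80 at 2 dp
f1_score <- function(p, r) {
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

# 0/0 convention: a class absent from both gold and prediction is vacuously
# perfect (100); a zero denominator with the class present on either side
# scores 0.
ratio100 <- function(num, den, vacuous = FALSE) {
  if (den == 0) (if (vacuous) 100 else 0) else 100 * num / den
}

#' Evaluate NER predictions against gold mentions
#'
#' Gold and predicted mentions are compared record by record under the
#' strict criterion (identical start, end, and label). Per-class counts
#' yield precision, recall, and F1; the `macro_*` averages are unweighted
#' means over the three classes (the convention behind a results table's
#' "Average" column), and `micro_*` are computed from pooled counts. A
#' class absent from both gold and prediction scores 100 (vacuous
#' agreement), so a perfect prediction always evaluates to 100 everywhere;
#' any other zero denominator scores 0.
#'
#' @param gold,predicted Lists of mention tables, one element per record,
#'   aligned by position.
#' @return An object of class `cpm_eval`: `per_class` data.frame (label,
#'   tp, fp, fn, precision, recall, f1) plus macro and micro aggregates.
#' @export
evaluate_ner <- function(gold, predicted) {
  if (inherits(gold, "data.frame")) gold <- list(gold)
  if (inherits(predicted, "data.frame")) predicted <- list(predicted)
  if (length(gold) != length(predicted))
    stop("gold and predicted must have the same number of records")
  tp <- fp <- fn <- stats::setNames(rep(0L, length(NER_LABELS)), NER_LABELS)
  key <- function(m) sprintf("%d:%d:%s", m$start, m$end, m$label)
  for (r in seq_along(gold)) {
    g <- gold[[r]]; p <- predicted[[r]]
    validate_mentions(g); validate_mentions(p)
    gk <- key(g); pk <- key(p)
    if (anyDuplicated(gk) || anyDuplicated(pk))
      stop(sprintf("duplicate mentions within record %d", r))
    for (lab in NER_LABELS) {
      gl <- gk[g$label == lab]; pl <- pk[p$label == lab]
      hit <- sum(pl %in% gl)
      tp[lab] <- tp[lab] + hit
      fp[lab] <- fp[lab] + length(pl) - hit
      fn[lab] <- fn[lab] + length(gl) - hit
    }
  }
  vac <- (tp + fp + fn) == 0L
  prec <- mapply(ratio100, tp, tp + fp, vac)
  rec <- mapply(ratio100, tp, tp + fn, vac)
  f1 <- f1_score(prec, rec)
  per_class <- data.frame(label = NER_LABELS, tp = as.integer(tp),
                          fp = as.integer(fp), fn = as.integer(fn),
                          precision = unname(prec), recall = unname(rec),
                          f1 = unname(f1), stringsAsFactors = FALSE)
  all_vac <- sum(tp + fp + fn) == 0L
  micro_p <- ratio100(sum(tp), sum(tp) + sum(fp), all_vac)
  micro_r <- ratio100(sum(tp), sum(tp) + sum(fn), all_vac)
  structure(list(per_class = per_class,
                 macro_precision = mean(prec), macro_recall = mean(rec),
                 macro_f1 = mean(f1),
                 micro_precision = micro_p, micro_recall = micro_r,
                 micro_f1 = f1_score(micro_p, micro_r)),
            class = "cpm_eval")
}

#' Aggregate a per-class metric table into its macro "Average" column
#'
#' Given per-class precision/recall/F1 percentages (e.g. the printed rows
#' of a published results table), computes the unweighted macro means.
#'
#' @param per_class A data.frame with columns `precision`, `recall`, `f1`
#'   (one row per class).
#' @return Named numeric: `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
#' @examples
#' tab <- data.frame(precision = c(78.98, 82.82, 86.57),
#'                   recall    = c(82.26, 81.56, 87.04),
#'                   f1        = c(80.58, 82.09, 86.80))
#' round(macro_average(tab), 2)
macro_average <- function(per_class) {
  stopifnot(all(c("precision", "recall", "f1") %in% names(per_class)))
  c(macro_precision = mean(per_class$precision),
    macro_recall = mean(per_class$recall),
    macro_f1 = mean(per_class$f1))
}

#' @export
print.cpm_eval <- function(x, digits = 2, ...) {
  cat("NER evaluation (strict span match, % scale)\n")
  d <- x$per_class
  d$precision <- round(d$precision, digits)
  d$recall <- round(d$recall, digits)
  d$f1 <- round(d$f1, digits)
  print(d, row.names = FALSE)
  cat(sprintf("macro: P=%.*f R=%.*f F1=%.*f\n", digits, x$macro_precision,
              digits, x$macro_recall, digits, x$macro_f1))
  cat(sprintf("micro: P=%.*f R=%.*f F1=%.*f\n", digits, x$micro_precision,
              digits, x$micro_recall, digits, x$micro_f1))
  invisible(x)
}
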