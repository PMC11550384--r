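#' AUC-ratio responsive-neuron classification
#'
#' Labels each neuron by the change in area under its trial-averaged dF/F
#' trace from the 10 s before to the 10 s after an event: `increased`
#' when post/pre AUC exceeds 1 + `change` (a > 50% increase by default),
#' `decreased` when it falls below 1 - `change`, `no_change` otherwise
#' (strict inequalities at both boundaries).
#'
#' The ratio is only meaningful when the baseline AUC is reliably
#' positive. A single robust threshold
#' `eps = 3 * mad(auc_pre)` (falling back to 1% of the baseline-window
#' length when the spread is zero, e.g. for a single record) decides the
#' regime: neurons with `auc_pre > eps` are classified by the ratio;
#' neurons whose baseline AUC is within noise of zero (or negative) are
#' classified by the difference `auc_post - auc_pre` against the same
#' `eps`, so the rule stays scale-invariant. Records with non-finite AUCs
#' are labelled `degenerate`.
#'
#' @param auc AUC table from [peri_auc()] (columns `neuron_id`,
#'   `auc_pre`, `auc_post`).
#' @param change Fractional change threshold (default 0.5, i.e. 50%).
#' @param pre_window_s Baseline window length in seconds, used for the
#'   zero-spread fallback; taken from the `pre_window_s` attribute of
#'   `auc` when present.
#' @return `auc` with added columns `effective_ratio` (post/pre where the
#'   ratio rule applied, `NA` otherwise) and `category` (factor:
#'   `increased`, `no_change`, `decreased`, `degenerate`).
#' @export
classify_responses <- function(auc, change = 0.5, pre_window_s = NULL) {
  stopifnot(all(c("neuron_id", "auc_pre", "auc_post") %in% names(auc)),
            change > 0)
  if (is.null(pre_window_s))
    pre_window_s <- attr(auc, "pre_window_s")
  if (is.null(pre_window_s)) pre_window_s <- 10
  eps_scale <- stats::mad(auc$auc_pre[is.finite(auc$auc_pre)])
  eps <- if (is.finite(eps_scale) && eps_scale > 0) 3 * eps_scale
         else 0.01 * pre_window_s
  cat_of <- function(pre, post) {
    if (!is.finite(pre) || !is.finite(post)) return("degenerate")
    if (pre > eps) {
      r <- post / pre
      if (r > 1 + change) "increased"
      else if (r < 1 - change) "decreased"
      else "no_change"
    } else {
      d <- post - pre
      if (d > eps) "increased"
      else if (d < -eps) "decreased"
      else "no_change"
    }
  }
  auc$effective_ratio <- ifelse(
    is.finite(auc$auc_pre) & auc$auc_pre > eps,
    auc$auc_post / auc$auc_pre, NA_real_)
  auc$category <- factor(
    mapply(cat_of, auc$auc_pre, auc$auc_post),
    levels = c("increased", "no_change", "decreased", "degenerate"))
  attr(auc, "eps") <- eps
  auc
}

#' Round-half-up percentage with one decimal
#'
#' Percentages are reported as `100 * count / total` rounded half-up to
#' one decimal (so 43.45 prints as 43.5, unlike base `round()`'s
#' half-to-even).
#'
#' @param count,total Non-negative numbers, `total > 0`.
#' @return Numeric percentage with one decimal.
#' @export
percent1 <- function(count, total) {
  stopifnot(total > 0)
  floor(1000 * count / total + 0.5) / 10
}

#' Population summary of response categories
#'
#' @param classifications Output of [classify_responses()] (one row per
#'   neuron).
#' @return Data frame `category`, `count`, `percent` (one-decimal,
#'   half-up) plus attribute `n_total`; percentages are of all classified
#'   neurons.
#' @export
summarize_population <- function(classifications) {
  stopifnot(nrow(classifications) > 0)
  if (anyDuplicated(classifications$neuron_id))
    stop("duplicate neuron_id in classifications")
  counts <- table(classifications$category)
  n <- nrow(classifications)
  out <- data.frame(category = names(counts),
                    count = as.integer(counts),
                    percent = percent1(as.integer(counts), n),
                    stringsAsFactors = FALSE)
  attr(out, "n_total") <- n
  out
}

#' Cue-overlap encoding table
#'
#' Partitions a common neuron universe by responsiveness (category
#' `increased`) to two cues, e.g. CS1/CS2-encoding vs CS2-only neurons.
#'
#' @param class_a,class_b Classification tables for the two cues over the
#'   same neurons.
#' @param labels Length-2 character vector naming the cues.
#' @return Data frame with rows `both`, `<a>_only`, `<b>_only`, `neither`
#'   and columns `count`, `percent_of_total`, plus
#'   `percent_of_<b>_responders` for the overlap row (share of cue-b
#'   responders that also respond to cue a).
#' @export
encode_overlap <- function(class_a, class_b, labels = c("CS1", "CS2")) {
  if (!setequal(class_a$neuron_id, class_b$neuron_id))
    stop("classifications cover different neuron universes")
  class_b <- class_b[match(class_a$neuron_id, class_b$neuron_id), ]
  a <- class_a$category == "increased"
  b <- class_b$category == "increased"
  n <- length(a)
  counts <- c(both = sum(a & b), a_only = sum(a & !b),
              b_only = sum(!a & b), neither = sum(!a & !b))
  out <- data.frame(
    group = c("both", paste0(labels[1L], "_only"),
              paste0(labels[2L], "_only"), "neither"),
    count = as.integer(counts),
    percent_of_total = percent1(as.integer(counts), n),
    stringsAsFactors = FALSE)
  attr(out, "n_total") <- n
  attr(out, "percent_of_b_responders") <-
    if (sum(b) > 0) percent1(counts[["both"]], sum(b)) else NA_real_
  out
}
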