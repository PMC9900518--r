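#' Relative amplification of a long-amplicon qPCR lane
#'
#' Normalizes the long-amplicon band intensity by the short-amplicon
#' (loading-control) band of the same gene, then expresses it relative to
#' the vehicle control, which is set to unity:
#' `(treated.long / treated.short) / (control.long / control.short)`.
#' The ratio is invariant to rescaling all intensities of a lane by a
#' positive constant, and a control measured against itself is exactly 1.
#'
#' @param treated,control single LA-qPCR records: one-row data.frames or
#'   lists with fields `gene`, `long_intensity`, `short_intensity`,
#'   `long_length_kb`, `short_length_kb` (and `is_control` for
#'   `control`).
#' @return dimensionless relative amplification in `(0, Inf)`.
#' @seealso [lesionsPer10kb()] for the Poisson inversion of this ratio.
#' @export
relativeAmplification <- function(treated, control) {
  g <- function(x, f) {
    v <- x[[f]]
    if (is.null(v) || length(v) != 1L) stop("missing field: ", f)
    v
  }
  if (g(treated, "gene") != g(control, "gene")) {
    stop("gene mismatch between treated and control records")
  }
  if (g(treated, "long_length_kb") != g(control, "long_length_kb") ||
    g(treated, "short_length_kb") != g(control, "short_length_kb")) {
    stop("amplicon length mismatch between treated and control records")
  }
  if (!is.null(control$is_control) && !isTRUE(as.logical(control$is_control))) {
    stop("control record must have is_control = TRUE")
  }
  ints <- c(
    g(treated, "long_intensity"), g(treated, "short_intensity"),
    g(control, "long_intensity"), g(control, "short_intensity")
  )
  if (any(!is.finite(ints)) || any(ints <= 0)) {
    stop("band intensities must be positive")
  }
  (ints[1] / ints[2]) / (ints[3] / ints[4])
}

#' Poisson zero-class lesion frequency
#'
#' Converts a relative amplification into a lesion frequency. Lesions
#' block the polymerase, so only zero-lesion template molecules amplify;
#' under a Poisson lesion distribution the amplifiable fraction is
#' `P(0) = exp(-lambda)`, giving `lambda_amplicon = -log(rel)` lesions
#' per long amplicon and `lesions_per_10kb = lambda * 10 / long_length_kb`.
#'
#' A relative amplification above 1 (treated amplifies better than
#' control — noise) yields a negative estimate, reported with
#' `flagged = TRUE` rather than clamped to zero so the noise structure
#' stays visible; summaries may clamp.
#'
#' With `correctShort = TRUE` the short amplicon is no longer assumed
#' lesion-free: the observed ratio is modeled as
#' `exp(-lambda10 * (L_long - L_short) / 10)`, which slightly raises the
#' estimate (by `L_long / (L_long - L_short)`). Off by default; the short
#' fragment's break probability is negligible at typical lengths.
#'
#' @param rel relative amplification from [relativeAmplification()]
#'   (`> 0`).
#' @param longLengthKb long-amplicon length in kb (e.g. 12.2 for POLB,
#'   10.4 for HPRT).
#' @param correctShort logical, see above.
#' @param shortLengthKb short-amplicon length in kb, required when
#'   `correctShort = TRUE`.
#' @return a one-row data.frame: `relativeAmplification`,
#'   `lambdaAmplicon`, `lesionsPer10kb`, `flagged`.
#' @examples
#' lesionsPer10kb(exp(-1.22), 12.2) # 1 lesion per 10 kb
#' @export
lesionsPer10kb <- function(rel, longLengthKb, correctShort = FALSE,
                           shortLengthKb = NULL) {
  if (!is.finite(rel) || rel <= 0) {
    stop("relative amplification must be > 0")
  }
  if (longLengthKb <= 0) stop("amplicon length must be > 0")
  if (correctShort) {
    if (is.null(shortLengthKb) || shortLengthKb <= 0 ||
      shortLengthKb >= longLengthKb) {
      stop("correctShort needs 0 < shortLengthKb < longLengthKb")
    }
    per10 <- -log(rel) * 10 / (longLengthKb - shortLengthKb)
    lam <- per10 * longLengthKb / 10
  } else {
    lam <- -log(rel)
    per10 <- lam * 10 / longLengthKb
  }
  data.frame(
    relativeAmplification = rel, lambdaAmplicon = lam,
    lesionsPer10kb = per10, flagged = rel > 1
  )
}

#' Read an LA-qPCR band-intensity table
#'
#' Expects a CSV with columns `gene`, `condition`, `replicate`,
#' `long_intensity`, `short_intensity`, `long_length_kb`,
#' `short_length_kb`, `is_control`.
#'
#' @param path CSV file path.
#' @return data.frame with those columns validated.
#' @export
readAmplificationTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(
    "gene", "condition", "replicate", "long_intensity",
    "short_intensity", "long_length_kb", "short_length_kb", "is_control"
  )
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  }
  df$is_control <- as.logical(df$is_control)
  if (any(df$long_intensity <= 0) || any(df$short_intensity <= 0)) {
    stop("band intensities must be positive")
  }
  if (any(df$long_length_kb <= df$short_length_kb)) {
    stop("long amplicon must be longer than short amplicon")
  }
  df
}

#' Estimate lesion frequencies for a full LA-qPCR table
#'
#' For each gene, the control ratio is the mean `long/short` over that
#' gene's control replicates; every lane is then expressed relative to it
#' and inverted to lesions per 10 kb. Replicates are estimated
#' individually, then summarized as mean +/- SEM per gene x condition.
#'
#' @param df a table as returned by [readAmplificationTable()].
#' @param correctShort passed to [lesionsPer10kb()].
#' @return list with `perReplicate` (one row per lane) and
#'   `perCondition` (mean, SEM, n of `lesionsPer10kb` and of
#'   `relativeAmplification` per gene x condition).
#' @export
estimateLesions <- function(df, correctShort = FALSE) {
  need <- c(
    "gene", "condition", "replicate", "long_intensity",
    "short_intensity", "long_length_kb", "short_length_kb", "is_control"
  )
  stopifnot(all(need %in% names(df)))
  out <- vector("list", nrow(df))
  for (gene in unique(df$gene)) {
    rows <- df$gene == gene
    ctl <- df[rows & df$is_control, , drop = FALSE]
    if (!nrow(ctl)) stop("gene ", gene, " has no control lanes")
    ctlRatio <- mean(ctl$long_intensity / ctl$short_intensity)
    for (i in which(rows)) {
      rel <- (df$long_intensity[i] / df$short_intensity[i]) / ctlRatio
      est <- lesionsPer10kb(rel, df$long_length_kb[i],
        correctShort = correctShort,
        shortLengthKb = if (correctShort) df$short_length_kb[i] else NULL
      )
      out[[i]] <- cbind(
        df[i, c("gene", "condition", "replicate"), drop = FALSE],
        est
      )
    }
  }
  per <- do.call(rbind, out)
  rownames(per) <- NULL
  key <- interaction(per$gene, per$condition, drop = TRUE)
  sem <- function(x) {
    if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  }
  agg <- do.call(rbind, lapply(split(per, key), function(d) {
    data.frame(
      gene = d$gene[1], condition = d$condition[1], n = nrow(d),
      meanLesionsPer10kb = mean(d$lesionsPer10kb),
      semLesionsPer10kb = sem(d$lesionsPer10kb),
      meanRelativeAmplification = mean(d$relativeAmplification),
      semRelativeAmplification = sem(d$relativeAmplification)
    )
  }))
  rownames(agg) <- NULL
  list(perReplicate = per, perCondition = agg)
}

#' Write lesion estimates to CSV
#'
#' @param est result of [estimateLesions()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"lesions"`).
#' @return invisibly, the two file paths written.
#' @export
writeLesionEstimates <- function(est, dir, prefix = "lesions") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(prefix, "_per_replicate.csv"))
  p2 <- file.path(dir, paste0(prefix, "_per_condition.csv"))
  utils::write.csv(est$perReplicate, p1, row.names = FALSE)
  utils::write.csv(est$perCondition, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
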