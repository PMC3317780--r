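# Test-retest reproducibility statistics: Dice similarity coefficient,
# within-subject coefficient of variation, one-way random-effects intraclass
# correlation, paired t-tests, Bland-Altman summaries, and report assembly.

#' Construct a subjects x sessions metric panel
#'
#' Rows are subjects, columns sessions (k per subject).  Rows containing
#' missing values are dropped (and counted), mirroring per-metric subject
#' exclusion; values are never imputed.
#'
#' @param values numeric matrix (subjects x sessions).
#' @param metric_name,tract_name,mode labels carried into reports.
#' @return object of class `metric_panel`.
#' @export
metric_panel <- function(values, metric_name = "", tract_name = "",
                         mode = "") {
  values <- as.matrix(values)
  complete <- rowSums(is.na(values)) == 0
  dropped <- sum(!complete)
  structure(list(values = values[complete, , drop = FALSE],
                 k = ncol(values), metric_name = metric_name,
                 tract_name = tract_name, mode = mode,
                 n_dropped = dropped),
            class = "metric_panel")
}

#' Dice similarity coefficient of two binary segmentations
#'
#' \deqn{DSC = 2 N(t_1 \cap t_2) / (N(t_1) + N(t_2))}
#' where N counts mask voxels; 1 for complete and 0 for no spatial overlap.
#'
#' @param t1,t2 `tract_segmentation` objects (or plain binary arrays) on
#'   identical grids.
#' @return DSC in [0, 1].
#' @export
dice <- function(t1, t2) {
  m1 <- if (inherits(t1, "tract_segmentation")) t1$mask else t1
  m2 <- if (inherits(t2, "tract_segmentation")) t2$mask else t2
  if (!all(dim(m1) == dim(m2))) stop("segmentations must share one grid")
  if (inherits(t1, "tract_segmentation") && inherits(t2, "tract_segmentation") &&
      max(abs(t1$grid_to_world - t2$grid_to_world)) > 1e-6)
    stop("segmentations must be in the same (common) space")
  n1 <- sum(m1)
  n2 <- sum(m2)
  if (n1 + n2 == 0) stop("Dice coefficient is undefined for two empty masks")
  2 * sum(m1 & m2) / (n1 + n2)
}

# one-way random-effects sums of squares of a subjects x sessions matrix
oneway_mean_squares <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  stopifnot(n >= 2, k >= 2)
  mi <- rowMeans(x)
  grand <- mean(x)
  list(bsmss = k * sum((mi - grand)^2) / (n - 1),
       wsmss = sum((x - mi)^2) / (n * (k - 1)),
       grand = grand, n = n, k = k)
}

#' Within-subject coefficient of variation
#'
#' COV = sigma_ws / mu, with sigma_ws the square root of the within-subject
#' mean sum of squares of the one-way layout (for k = 2 this equals
#' sqrt(sum(d_i^2) / (2 n)) over paired differences) and mu the grand mean
#' over all cells.
#'
#' @param panel `metric_panel` (or plain subjects x sessions matrix).
#' @return COV (dimensionless, >= 0).
#' @export
cov_within_subject <- function(panel) {
  x <- if (inherits(panel, "metric_panel")) panel$values else as.matrix(panel)
  ms <- oneway_mean_squares(x)
  if (ms$grand == 0) stop("COV is undefined when the population mean is 0")
  sqrt(ms$wsmss) / ms$grand
}

#' One-way random-effects intraclass correlation coefficient
#'
#' \deqn{ICC = (BSMSS - WSMSS) / (BSMSS + (k - 1) WSMSS)}
#' with BSMSS/WSMSS the between/within-subject mean sums of squares and k
#' the number of sessions.  Ranges from -1 (no reliability, BSMSS = 0) to 1
#' (identical test and retest, WSMSS = 0).
#'
#' @param panel `metric_panel` (or plain subjects x sessions matrix).
#' @return ICC in [-1, 1].
#' @export
icc <- function(panel) {
  x <- if (inherits(panel, "metric_panel")) panel$values else as.matrix(panel)
  ms <- oneway_mean_squares(x)
  den <- ms$bsmss + (ms$k - 1) * ms$wsmss
  if (den == 0) stop("ICC is undefined when all values are identical")
  (ms$bsmss - ms$wsmss) / den
}

#' Paired two-sided t-test
#'
#' Standard paired t on per-subject differences (delegates to
#' [stats::t.test()]).  With zero difference variance the p-value is
#' undefined and flagged.
#'
#' @param a,b equal-length numeric vectors (one value per subject).
#' @return list with `t`, `p`, `mean_diff`, `flag_zero_variance`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (sd(d) == 0) {
    return(list(t = NA_real_, p = NA_real_, mean_diff = mean(d),
                flag_zero_variance = TRUE))
  }
  ht <- t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, mean_diff = mean(d),
       flag_zero_variance = FALSE)
}

#' Bland-Altman agreement summary for a test-retest panel
#'
#' Per subject, the between-session mean and difference; bias (mean
#' difference), 95% limits of agreement (bias +/- 1.96 SD), and the slope
#' of difference on mean with its p-value (the independence check: precision
#' should not depend on the metric value).
#'
#' @param panel `metric_panel` with k = 2 sessions.
#' @return list with `pairs` (data.frame mean/difference), `bias`,
#'   `loa_low`, `loa_high`, `slope`, `slope_p`.
#' @export
bland_altman <- function(panel) {
  x <- if (inherits(panel, "metric_panel")) panel$values else as.matrix(panel)
  stopifnot(ncol(x) == 2)
  m <- (x[, 1] + x[, 2]) / 2
  d <- x[, 1] - x[, 2]
  bias <- mean(d)
  s <- sd(d)
  slope <- NA_real_
  slope_p <- NA_real_
  if (nrow(x) >= 3 && sd(m) > 0 && sd(d) > 0) {
    fit <- summary(lm(d ~ m))$coefficients
    if (nrow(fit) == 2) {
      slope <- fit[2, 1]
      slope_p <- fit[2, 4]
    }
  }
  list(pairs = data.frame(mean = m, difference = d), bias = bias,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       slope = slope, slope_p = slope_p)
}

#' Assemble the reproducibility report tables
#'
#' Produces the morphology block (per tract x mode: mean DSC, between-subject
#' SD, paired proximal-vs-extended p) and the metric block (per tract x mode
#' x metric: mean, sigma_ws, sigma_bs, COV, ICC).
#'
#' @param dsc_table data.frame with columns `tract`, `mode`, `subject`,
#'   `dsc` (one row per subject per mode).
#' @param panels list of `metric_panel` objects (one per tract x mode x
#'   metric).
#' @return object of class `repro_report`: `dsc` and `metrics` data.frames.
#' @export
build_report <- function(dsc_table, panels) {
  stopifnot(all(c("tract", "mode", "subject", "dsc") %in% names(dsc_table)))
  dsc_rows <- list()
  for (tr in unique(dsc_table$tract)) {
    sub <- dsc_table[dsc_table$tract == tr, ]
    row <- list(tract = tr)
    for (md in c("proximal", "extended")) {
      v <- sub$dsc[sub$mode == md]
      row[[paste0("dsc_mean_", md)]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0("dsc_sd_", md)]] <- if (length(v) > 1) sd(v) else NA_real_
    }
    pv <- NA_real_
    prox <- sub[sub$mode == "proximal", ]
    extd <- sub[sub$mode == "extended", ]
    common <- intersect(prox$subject, extd$subject)
    if (length(common) >= 2) {
      pt <- paired_t(prox$dsc[match(common, prox$subject)],
                     extd$dsc[match(common, extd$subject)])
      pv <- pt$p
    }
    row$p_prox_vs_ext <- pv
    dsc_rows[[length(dsc_rows) + 1L]] <- as.data.frame(row)
  }
  dsc_df <- do.call(rbind, dsc_rows)

  met_rows <- lapply(panels, function(p) {
    ms <- oneway_mean_squares(p$values)
    data.frame(tract = p$tract_name, mode = p$mode, metric = p$metric_name,
               n_subjects = nrow(p$values), n_dropped = p$n_dropped,
               mean = ms$grand,
               sigma_ws = sqrt(ms$wsmss),
               sigma_bs = sd(rowMeans(p$values)),
               cov = cov_within_subject(p),
               icc = icc(p))
  })
  metrics_df <- do.call(rbind, met_rows)

  # paired proximal-vs-extended test per tract x metric (subjects' session
  # means), attached to the proximal row of each pair
  metrics_df$p_prox_vs_ext <- NA_real_
  key <- paste(metrics_df$tract, metrics_df$metric)
  for (kk in unique(key)) {
    idx <- which(key == kk)
    ip <- idx[metrics_df$mode[idx] == "proximal"]
    ie <- idx[metrics_df$mode[idx] == "extended"]
    if (length(ip) == 1 && length(ie) == 1) {
      pp <- panels[[ip]]
      pe <- panels[[ie]]
      n <- min(nrow(pp$values), nrow(pe$values))
      if (n >= 2 && nrow(pp$values) == nrow(pe$values)) {
        pt <- paired_t(rowMeans(pp$values), rowMeans(pe$values))
        metrics_df$p_prox_vs_ext[c(ip, ie)] <- pt$p
      }
    }
  }
  structure(list(dsc = dsc_df, metrics = metrics_df), class = "repro_report")
}

#' @export
print.repro_report <- function(x, ...) {
  cat("repro_report\n-- morphology (DSC) --\n")
  print(x$dsc, row.names = FALSE, digits = 3)
  cat("-- tract metrics --\n")
  print(x$metrics, row.names = FALSE, digits = 3)
  invisible(x)
}
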