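# Study-style statistics: mean +/- SD (min-max) descriptives, exact
# small-sample Mann-Whitney comparisons between lateralization conditions,
# and intraclass correlation agreement for repeated segmentations.

#' Descriptive statistics
#'
#' @param x numeric vector (n >= 1; the sample SD needs n >= 2).
#' @return An object of class `descriptives` with `mean`, `sd` (n-1
#'   denominator), `min`, `max`, `n`.
#' @export
descriptives <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0 || all(is.na(x))) stop("empty sample")
  x <- x[!is.na(x)]
  structure(list(mean = mean(x),
                 sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
                 min = min(x), max = max(x), n = length(x)),
            class = "descriptives")
}

#' Render descriptives as "mean+/-SD (min-max)"
#'
#' @param d a [descriptives()].
#' @param digits decimals (default 2).
#' @return character scalar.
#' @export
format_descriptives <- function(d, digits = 2) {
  stopifnot(inherits(d, "descriptives"))
  sprintf("%.*f±%.*f (%.*g–%.*g)", digits, d$mean, digits, d$sd,
          digits + 2, d$min, digits + 2, d$max)
}

#' @export
print.descriptives <- function(x, ...) {
  cat(sprintf("<descriptives> n = %d: %s\n", x$n, format_descriptives(x)))
  invisible(x)
}

#' Exact Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. For combined sample
#' sizes up to `exact_max` the null distribution of U is obtained by full
#' enumeration of all `choose(n1 + n2, n1)` group assignments of the
#' observed midranks, so ties are handled exactly; the two-sided p doubles
#' the smaller one-sided tail, capped at 1. Beyond `exact_max` a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' The smallest achievable two-sided p at n1 = n2 = 7 (complete
#' separation) is 2/3432.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_max maximum n1 + n2 for exact enumeration (default 20).
#' @return list with `statistic` (U for the first sample), `p_value`,
#'   `method` (`"exact"` or `"normal"`), `n1`, `n2`.
#' @export
mann_whitney_exact <- function(x, y, exact_max = 20) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_max) {
    picks <- utils::combn(n1 + n2, n1)
    rsums <- colSums(matrix(r[picks], nrow = n1))
    Unull <- rsums - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_lo <- mean(Unull <= U + eps)
    p_hi <- mean(Unull >= U - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = U, p_value = p, method = method, n1 = n1, n2 = n2)
}

#' Intraclass correlation for rater agreement
#'
#' Single-measure ICC from the two-way mean-squares decomposition of a
#' subjects x raters matrix. `"ICC2"` (two-way random effects, absolute
#' agreement, the default) and `"ICC3"` (two-way mixed, consistency) are
#' available; both are reported by [agreement_table()] for transparency.
#'
#' @param ratings numeric matrix, subjects in rows (>= 2), raters/sessions
#'   in columns (>= 2).
#' @param model `"ICC2"` or `"ICC3"`.
#' @param label optional comparison label carried into the result.
#' @param target optional description of the rated quantity.
#' @return An object of class `icc_result` with `icc`, `model`, `label`,
#'   `target` and the mean squares `msr`, `msc`, `mse`.
#' @export
icc_agreement <- function(ratings, model = c("ICC2", "ICC3"),
                          label = "", target = "") {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) {
    stop("ICC needs at least 2 subjects and 2 ratings per subject")
  }
  if (anyNA(ratings)) stop("ratings must be complete")
  gm <- mean(ratings)
  rowm <- rowMeans(ratings)
  colm <- colMeans(ratings)
  ssr <- k * sum((rowm - gm)^2)
  ssc <- n * sum((colm - gm)^2)
  sst <- sum((ratings - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps * max(1, abs(gm))^2) {
    stop("zero between-subject variance: ICC is undefined for these ratings")
  }
  icc <- if (model == "ICC2") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  structure(list(icc = icc, model = model, label = label, target = target,
                 msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s%s%s = %.4f (%d subjects x %d ratings)\n",
              if (nzchar(x$label)) paste0(x$label, ": ") else "",
              x$model,
              if (nzchar(x$target)) paste0(" [", x$target, "]") else "",
              x$icc, x$n, x$k))
  invisible(x)
}

#' Simulated inter-/intra-rater segmentation study
#'
#' Emulates the reliability protocol: two raters segment every patient
#' twice (a week apart); each repeat is the true labeled volume warped by a
#' smooth random displacement field. From each repeat the deltoid internal
#' surface is re-extracted and the ILSS refitted, yielding per-repeat model
#' volume (mm^3 of all labeled structures) and ILSS radius.
#'
#' @param patients list of [shoulder_params()].
#' @param noise_sd boundary displacement SD in mm per repeat segmentation.
#' @param seed RNG seed.
#' @param config [fit_config()] for the radius refits.
#' @return tibble with columns `patient`, `rater`, `week`,
#'   `model_volume_mm3`, `ilss_radius`.
#' @export
simulate_rater_study <- function(patients, noise_sd = 0.2, seed = 1L,
                                 config = fit_config()) {
  rows <- list()
  for (i in seq_along(patients)) {
    params <- patients[[i]]
    base <- generate_shoulder(params, seed = seed + 100 * i,
                              with_volume = TRUE)
    for (rater in 1:2) for (week in 1:2) {
      rep_seed <- seed + 100 * i + 10 * rater + week
      vol <- perturb_segmentation(base$volume, noise_sd, seed = rep_seed)
      surf <- extract_internal_surface(
        vol, label = 1L, toward = params$implant_center,
        max_distance = 1.3 * params$implant_radius)
      fit <- iterate_fit(surf, config)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient = i, rater = rater, week = week,
        model_volume_mm3 = sum(vol$voxels > 0) * prod(vol$spacing),
        ilss_radius = fit$sphere$radius)
    }
  }
  do.call(rbind, rows)
}

#' Agreement table across raters and sessions
#'
#' Intra-rater (week 1 vs week 2, per rater) and inter-rater (rater 1 vs
#' 2, per week) ICCs over patients, for the 3D model volume and the ILSS
#' radius.
#'
#' @param study output of [simulate_rater_study()].
#' @param model ICC model passed to [icc_agreement()].
#' @return tibble with `comparison`, `target`, `icc`, `model`.
#' @export
agreement_table <- function(study, model = "ICC2") {
  pick <- function(rater = NULL, week = NULL, col) {
    sel <- if (is.null(rater)) {
      sapply(1:2, function(r)
        study[[col]][study$rater == r & study$week == week])
    } else {
      sapply(1:2, function(w)
        study[[col]][study$rater == rater & study$week == w])
    }
    matrix(sel, ncol = 2)
  }
  specs <- list(
    list(lab = "Rater 1 (week 1 vs 2)", rater = 1, week = NULL),
    list(lab = "Rater 2 (week 1 vs 2)", rater = 2, week = NULL),
    list(lab = "Rater 1 vs 2 (week 1)", rater = NULL, week = 1),
    list(lab = "Rater 1 vs 2 (week 2)", rater = NULL, week = 2))
  targets <- c(model_volume_mm3 = "3D model volume",
               ilss_radius = "ILSS radius")
  rows <- list()
  for (s in specs) for (col in names(targets)) {
    icc <- icc_agreement(pick(s$rater, s$week, col), model = model,
                         label = s$lab, target = targets[[col]])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      comparison = s$lab, target = targets[[col]], icc = icc$icc,
      model = model)
  }
  do.call(rbind, rows)
}

#' Build the study-style report tables
#'
#' From a [run_pipeline()] result table: per-slice, per-offset
#' descriptives of T, E, CER and DMA (the biomechanical-parameters table
#' layout) and pairwise Mann-Whitney comparisons between every pair of
#' offsets (0vs6, 0vs9, 0vs12, 6vs9, 6vs12, 9vs12 for the default
#' offsets). No multiple-testing correction is applied (alpha = 0.05 per
#' test).
#'
#' @param results tibble from [run_pipeline()].
#' @param parameters result columns to tabulate.
#' @return list with tibbles `descriptives` (slice, offset, parameter,
#'   mean, sd, min, max, n, formatted) and `comparisons` (parameter, slice,
#'   one p-value column per offset pair).
#' @export
build_tables <- function(results,
                         parameters = c("T", "E", "cer", "dma")) {
  stopifnot(all(c("slice", "offset") %in% names(results)),
            all(parameters %in% names(results)))
  offsets <- sort(unique(results$offset))
  slices <- sort(unique(results$slice))
  drows <- list()
  for (p in parameters) for (s in slices) for (o in offsets) {
    v <- results[[p]][results$slice == s & results$offset == o]
    if (length(v) == 0) next
    d <- descriptives(v)
    drows[[length(drows) + 1L]] <- tibble::tibble(
      parameter = p, slice = s, offset = o,
      mean = d$mean, sd = d$sd, min = d$min, max = d$max, n = d$n,
      formatted = format_descriptives(d))
  }
  pairs <- utils::combn(offsets, 2)
  crows <- list()
  for (p in parameters) for (s in slices) {
    row <- tibble::tibble(parameter = p, slice = s)
    for (j in seq_len(ncol(pairs))) {
      a <- results[[p]][results$slice == s & results$offset == pairs[1, j]]
      b <- results[[p]][results$slice == s & results$offset == pairs[2, j]]
      nm <- sprintf("p_%gvs%g", pairs[1, j], pairs[2, j])
      row[[nm]] <- if (length(a) && length(b)) {
        mann_whitney_exact(a, b)$p_value
      } else NA_real_
    }
    crows[[length(crows) + 1L]] <- row
  }
  list(descriptives = do.call(rbind, drows),
       comparisons = do.call(rbind, crows))
}

#' Write report tables to CSV
#'
#' @param tables list from [build_tables()] (and optionally an
#'   `agreement` tibble from [agreement_table()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_report <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
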