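# Sample- and line-level phenotype statistics: per-sample aggregates
# (mean, percentiles, relative standard deviation), genotype-level
# exclusion bookkeeping, the paired treatment test, and broad-sense
# heritability from one-way variance components.

#' Relative standard deviation
#'
#' The ratio of the (n-1) sample standard deviation to the mean; a
#' scale-free dispersion measure of fruit uniformity within a sample.
#'
#' @param values numeric vector with nonzero mean.
#' @return sd / mean.
#' @export
rsd <- function(values) {
  m <- mean(values)
  if (!is.finite(m) || m == 0) stop("rsd undefined for zero mean")
  sd(values) / m
}

DEFAULT_PERCENTILES <- c(5, 25, 50, 75, 95)

#' Aggregate instance traits within one sample
#'
#' Computes mean, percentiles (linear interpolation between order
#' statistics) and RSD for each trait over the accepted instances of a
#' sample, plus acceptance bookkeeping. Samples with no accepted instance
#' are reported as missing (`NA` statistics), not zero.
#'
#' @param traits_df rows of an instance trait table (see
#'   [extract_traits_batch()]) belonging to one sample.
#' @param percentiles percentile levels in (0, 100).
#' @return one-row-per-trait data.frame with columns `trait`, `mean`,
#'   `p<level>`..., `rsd`, `n_accepted`, `n_rejected`, `rejection_rate`.
#' @export
aggregate_sample <- function(traits_df, percentiles = DEFAULT_PERCENTILES) {
  acc <- traits_df[traits_df$qc_status == "accepted", , drop = FALSE]
  n_acc <- nrow(acc)
  n_rej <- nrow(traits_df) - n_acc
  out <- vector("list", length(TRAIT_COLS))
  for (k in seq_along(TRAIT_COLS)) {
    tr <- TRAIT_COLS[k]
    v <- acc[[tr]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      stats <- c(mean = NA_real_,
                 setNames(rep(NA_real_, length(percentiles)),
                          paste0("p", percentiles)),
                 rsd = NA_real_)
    } else {
      q <- quantile(v, percentiles / 100, type = 7, names = FALSE)
      stats <- c(mean = mean(v),
                 setNames(q, paste0("p", percentiles)),
                 rsd = if (length(v) > 1L && mean(v) != 0) rsd(v) else
                   if (length(v) == 1L) NA_real_ else NA_real_)
    }
    out[[k]] <- data.frame(trait = tr, t(stats),
                           n_accepted = n_acc, n_rejected = n_rej,
                           rejection_rate = if (n_acc + n_rej > 0L)
                             n_rej / (n_acc + n_rej) else NA_real_,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate instance traits for all samples in a trait table
#'
#' @param traits_df full instance trait table with a `sample_id` column.
#' @inheritParams aggregate_sample
#' @return data.frame with a `sample_id` column and one row per sample and
#'   trait.
#' @export
aggregate_samples <- function(traits_df, percentiles = DEFAULT_PERCENTILES) {
  parts <- lapply(split(traits_df, traits_df$sample_id), aggregate_sample,
                  percentiles = percentiles)
  out <- do.call(rbind, Map(function(sid, df) cbind(sample_id = sid, df),
                            names(parts), parts))
  rownames(out) <- NULL
  out
}

#' Remove all samples of flagged genotypes
#'
#' Pot-level exclusion: a genotype flagged for aberrant plants (e.g., a
#' high number of aborting fruits) has *all* of its replicate samples
#' removed, across every batch and treatment.
#'
#' @param samples data.frame with a `genotype` column (e.g., a manifest).
#' @param flagged_genotypes character vector of genotypes to drop.
#' @return list with `kept` (data.frame) and `removed_count`.
#' @export
exclude_flagged <- function(samples, flagged_genotypes) {
  unknown <- setdiff(flagged_genotypes, samples$genotype)
  if (length(unknown) > 0L)
    warning("flag(s) for genotype(s) absent from the samples: ",
            paste(unknown, collapse = ", "))
  drop <- samples$genotype %in% flagged_genotypes
  list(kept = samples[!drop, , drop = FALSE],
       removed_count = sum(drop))
}

#' Paired treatment test on per-genotype summaries
#'
#' Pairs the two treatments within genotype: each genotype contributes its
#' mean value per treatment, and a classical paired t-test is run on the
#' per-genotype differences (`group` minus `isolation`). Genotypes
#' observed in only one treatment are dropped and counted.
#'
#' @param df data.frame with columns `line`, `treatment`
#'   (`isolation`/`group`) and `value` (e.g., a per-sample aggregate
#'   metric).
#' @return list with `t`, `df`, `p`, `n_pairs`, `n_dropped`,
#'   `mean_difference`, and `degenerate` (TRUE when all differences are
#'   identical, leaving the statistic undefined).
#' @export
paired_treatment_test <- function(df) {
  stopifnot(all(c("line", "treatment", "value") %in% names(df)))
  bad <- setdiff(unique(df$treatment), c("isolation", "group"))
  if (length(bad) > 0L)
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "))
  ag <- aggregate(value ~ line + treatment, data = df, FUN = mean)
  iso <- ag[ag$treatment == "isolation", c("line", "value")]
  grp <- ag[ag$treatment == "group", c("line", "value")]
  merged <- merge(iso, grp, by = "line", suffixes = c("_iso", "_grp"))
  n_pairs <- nrow(merged)
  n_dropped <- length(unique(df$line)) - n_pairs
  if (n_pairs < 2L) stop("need at least 2 genotypes present in both treatments")
  diffs <- merged$value_grp - merged$value_iso
  if (sd(diffs) == 0)
    return(list(t = NA_real_, df = n_pairs - 1L, p = NA_real_,
                n_pairs = n_pairs, n_dropped = n_dropped,
                mean_difference = mean(diffs), degenerate = TRUE))
  tt <- t.test(merged$value_grp, merged$value_iso, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_pairs = n_pairs, n_dropped = n_dropped,
       mean_difference = mean(diffs), degenerate = FALSE)
}

#' Broad-sense heritability (repeatability) from one-way ANOVA
#'
#' Method-of-moments variance components from the one-way classification
#' of replicate values within genotype lines (a single treatment at a
#' time): `H2 = sigma2_line / (sigma2_line + sigma2_resid)`, where
#' `sigma2_line = (MSB - MSW) / n0` and `n0` is the standard unbalanced
#' correction `(N - sum(n_i^2) / N) / (a - 1)`. The estimate is clipped to
#' `[0, 1]`.
#'
#' @param df data.frame with columns `line` and `value`; at least 2 lines,
#'   and replicate observations within lines.
#' @return list with `H2`, `sigma2_line`, `sigma2_resid`, `n_lines`, `n0`.
#' @export
heritability_estimate <- function(df) {
  stopifnot(all(c("line", "value") %in% names(df)))
  v <- split(df$value, df$line)
  v <- v[lengths(v) > 0L]
  a <- length(v)
  if (a < 2L) stop("need at least 2 lines")
  ni <- lengths(v)
  N <- sum(ni)
  if (N <= a) stop("need replicate observations within lines")
  means <- vapply(v, mean, numeric(1L))
  grand <- sum(ni * means) / N
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum(vapply(v, function(x) sum((x - mean(x))^2), numeric(1L)))
  msb <- ssb / (a - 1L)
  msw <- ssw / (N - a)
  n0 <- (N - sum(ni^2) / N) / (a - 1L)
  s2_line <- max(0, (msb - msw) / n0)
  h2 <- s2_line / (s2_line + msw)
  list(H2 = min(1, max(0, h2)), sigma2_line = s2_line, sigma2_resid = msw,
       n_lines = a, n0 = n0)
}

#' Export mapping-ready phenotype tables
#'
#' Writes the two-file layout consumed by multiparent QTL mapping
#' software: a phenotype CSV (one row per line x treatment, one column per
#' trait metric) and a covariate CSV (line, treatment, batches the line's
#' samples came from).
#'
#' @param sample_aggregates data.frame from [aggregate_samples()].
#' @param manifest manifest data.frame linking `sample_id` to `genotype`,
#'   `treatment` and `batch`.
#' @param dir output directory (created if needed).
#' @param metrics statistic columns of `sample_aggregates` to export.
#' @return invisible character vector of the two file paths.
#' @export
export_qtl_tables <- function(sample_aggregates, manifest, dir,
                              metrics = c("mean", "p95", "rsd")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- merge(sample_aggregates,
              manifest[, c("sample_id", "genotype", "treatment", "batch")],
              by = "sample_id")
  pheno <- NULL
  for (m in metrics) {
    ag <- aggregate(df[[m]],
                    by = list(line = df$genotype, treatment = df$treatment,
                              trait = df$trait),
                    FUN = mean, na.rm = TRUE)
    ag$metric <- paste(ag$trait, m, sep = "_")
    ag <- ag[, c("line", "treatment", "metric", "x")]
    pheno <- rbind(pheno, ag)
  }
  wide <- reshape(pheno, idvar = c("line", "treatment"),
                  timevar = "metric", direction = "wide")
  names(wide) <- sub("^x\\.", "", names(wide))
  wide <- wide[order(wide$line, wide$treatment), ]
  covar <- aggregate(batch ~ genotype + treatment, data = df,
                     FUN = function(b) paste(sort(unique(b)), collapse = ";"))
  names(covar)[names(covar) == "genotype"] <- "line"
  p1 <- file.path(dir, "phenotypes.csv")
  p2 <- file.path(dir, "covariates.csv")
  write.csv(wide, p1, row.names = FALSE, na = "")
  write.csv(covar, p2, row.names = FALSE, na = "")
  invisible(c(p1, p2))
}
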