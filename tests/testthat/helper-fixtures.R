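# Shared fixture builders: tiny in-code datasets, no files on disk.

tiny_annotation <- function() {
  genome_annotation(
    data.frame(
      gene_id = c("g1", "g2", "g3"),
      chrom = c("chr1", "chr1", "chr2"),
      start = c(5000, 20000, 3000),
      end = c(8000, 22000, 4500),
      strand = c("+", "-", "+"),
      stringsAsFactors = FALSE
    ),
    c(chr1 = 50000, chr2 = 50000)
  )
}

# A GeneSignal frame with chosen per-gene densities (window length fixed so
# density fully determines signal_sum).
signals_from_densities <- function(densities_by_mark, window_len = 1000) {
  out <- do.call(rbind, lapply(names(densities_by_mark), function(mk) {
    d <- densities_by_mark[[mk]]
    data.frame(
      gene_id = names(d),
      mark_name = mk,
      signal_sum = unname(d) * window_len,
      window_len = window_len,
      density = unname(d),
      stringsAsFactors = FALSE
    )
  }))
  class(out) <- c("GeneSignal", "data.frame")
  out
}

# Independent hypergeometric enumeration oracle for the two-sided Fisher test
# (relative tie tolerance matching the implementation contract).
fisher_enum_oracle <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1.0)
  x <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(x, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Closed-form BH step-up oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force per-bp accumulation oracle for window signal.
per_bp_signal_oracle <- function(win_start, win_end, bins) {
  total <- 0
  for (i in seq_len(nrow(bins))) {
    ov <- min(win_end, bins$end[i]) - max(win_start, bins$start[i])
    if (ov > 0) {
      per_bp <- bins$value[i] / (bins$end[i] - bins$start[i])
      total <- total + per_bp * ov
    }
  }
  total
}

# Closed-form balanced three-way ANOVA oracle from marginal cell means.
anova3_oracle <- function(obs) {
  obs$genotype <- factor(obs$genotype)
  obs$treatment <- factor(obs$treatment)
  obs$time <- factor(obs$time)
  n <- nrow(obs)
  grand <- mean(obs$response)
  mean_by <- function(...) {
    f <- interaction(..., drop = FALSE)
    tapply(obs$response, f, mean)
  }
  count_by <- function(...) {
    f <- interaction(..., drop = FALSE)
    tapply(obs$response, f, length)
  }
  ss_means <- function(means, counts) sum(counts * (means - grand)^2)
  ss_g <- ss_means(mean_by(obs$genotype), count_by(obs$genotype))
  ss_t <- ss_means(mean_by(obs$treatment), count_by(obs$treatment))
  ss_d <- ss_means(mean_by(obs$time), count_by(obs$time))
  ss_gt <- ss_means(mean_by(obs$genotype, obs$treatment),
                    count_by(obs$genotype, obs$treatment)) - ss_g - ss_t
  ss_gd <- ss_means(mean_by(obs$genotype, obs$time),
                    count_by(obs$genotype, obs$time)) - ss_g - ss_d
  ss_td <- ss_means(mean_by(obs$treatment, obs$time),
                    count_by(obs$treatment, obs$time)) - ss_t - ss_d
  ss_cells <- ss_means(mean_by(obs$genotype, obs$treatment, obs$time),
                       count_by(obs$genotype, obs$treatment, obs$time))
  ss_gtd <- ss_cells - ss_g - ss_t - ss_d - ss_gt - ss_gd - ss_td
  ss_res <- sum((obs$response - ave(obs$response,
                                    obs$genotype, obs$treatment,
                                    obs$time))^2)
  a <- nlevels(obs$genotype); b <- nlevels(obs$treatment)
  d <- nlevels(obs$time)
  df <- c(a - 1, b - 1, d - 1, (a - 1) * (b - 1), (a - 1) * (d - 1),
          (b - 1) * (d - 1), (a - 1) * (b - 1) * (d - 1), n - a * b * d)
  ss <- c(ss_g, ss_t, ss_d, ss_gt, ss_gd, ss_td, ss_gtd, ss_res)
  ms <- ss / df
  f_stat <- c(ms[1:7] / ms[8], NA)
  data.frame(
    term = c("genotype", "treatment", "time", "genotype:treatment",
             "genotype:time", "treatment:time", "genotype:treatment:time",
             "Residuals"),
    df = df, sum_sq = ss, mean_sq = ms, F = f_stat,
    stringsAsFactors = FALSE
  )
}

# Small simulation config for fast Monte-Carlo loops.
small_sim_config <- function(seed, ...) {
  pw <- data.frame(
    pathway_id = sprintf("PWY%02d", 1:4),
    domain_id = c("specialized", "specialized", "amino-acid", "lipid"),
    n_genes = 15L,
    stringsAsFactors = FALSE
  )
  pw$H3K27me3 <- 1
  pw$H3K18ac <- 1
  sim_config(seed = seed, n_chroms = 1L, chrom_length_bp = 6e5,
             n_genes = 120L, bin_size_bp = 200L, pathways = pw, ...)
}
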