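# Shared fixture builders and independent oracle implementations.

# small lane with a clean positive titration (count+1 = 8 * conc exactly)
make_lane <- function(sample_id = "S1", lane_id = "1",
                      fov_count = 555L, fov_counted = 540L,
                      binding_density = 1.0,
                      gene_counts = c(G01 = 120L, G02 = 340L, G03 = 55L),
                      hk_counts = c(C1 = 900L, C2 = 1100L),
                      pos_counts = c(1023L, 255L, 63L, 15L, 3L, 0L),
                      neg_counts = c(0L, 1L, 0L, 1L, 0L, 0L, 1L, 0L)) {
  probes <- data.frame(
    code_class = c(rep("Endogenous", length(gene_counts)),
                   rep("Housekeeping", length(hk_counts)),
                   rep("Positive", length(pos_counts)),
                   rep("Negative", length(neg_counts))),
    name = c(names(gene_counts), names(hk_counts),
             sprintf("POS_%s(%s)", LETTERS[1:6],
                     c("128", "32", "8", "2", "0.5", "0.125")),
             sprintf("NEG_%s", LETTERS[seq_along(neg_counts)])),
    accession = "SYN", stringsAsFactors = FALSE)
  probes$count <- c(gene_counts, hk_counts, pos_counts, neg_counts)
  rcc_lane(lane_id, sample_id, fov_count, fov_counted, binding_density,
           probes)
}

# oracle: Spearman distance via explicit rank-then-Pearson
oracle_spearman_dist <- function(x, centroid) {
  1 - stats::cor(rank(x), rank(centroid), method = "pearson")
}

oracle_classify <- function(x, model) {
  x <- x[model$genes] - stats::median(x[model$genes])
  dl <- oracle_spearman_dist(x, model$centroid_low)
  dh <- oracle_spearman_dist(x, model$centroid_high)
  list(label = if (dh < dl) "high" else "low", dist_low = dl,
       dist_high = dh)
}

# oracle: geNorm M by explicit double loop over gene pairs and samples
oracle_genorm_m <- function(v) {
  lv <- log2(v)
  k <- nrow(v)
  m <- numeric(k)
  for (j in 1:k) {
    total <- 0
    for (i in 1:k) {
      if (i == j) next
      ratios <- numeric(ncol(v))
      for (s in 1:ncol(v)) ratios[s] <- lv[j, s] - lv[i, s]
      total <- total + stats::sd(ratios)
    }
    m[j] <- total / (k - 1)
  }
  stats::setNames(m, rownames(v))
}

# oracle: Cox partial log-likelihood for one covariate, no tied times
oracle_cox_pl <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_beta <- function(time, event, x, grid = seq(-5, 5, by = 1e-4)) {
  ll <- vapply(grid, oracle_cox_pl, numeric(1), time = time,
               event = event, x = x)
  grid[which.max(ll)]
}

# oracle: Harrell's C by exhaustive pair enumeration
oracle_c_index <- function(time, event, risk) {
  conc <- disc <- tied <- 0
  n <- length(time)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    # usable iff the earlier time is an event
    first <- if (time[i] < time[j]) i else if (time[j] < time[i]) j else NA
    if (is.na(first) || event[first] == 0) next
    second <- if (first == i) j else i
    if (risk[first] > risk[second]) conc <- conc + 1
    else if (risk[first] < risk[second]) disc <- disc + 1
    else tied <- tied + 1
  }
  (conc + 0.5 * tied) / (conc + disc + tied)
}

# oracle: two-stage adaptive step-up built on stats::p.adjust("BH")
oracle_two_stage <- function(p, q) {
  q1 <- q / (1 + q)
  r1 <- sum(stats::p.adjust(p, "BH") <= q1)
  m0 <- length(p) - r1
  if (m0 == 0) return(rep(TRUE, length(p)))
  stats::p.adjust(p, "BH") <= q1 * length(p) / m0
}

true_labels <- function(cohort) {
  stats::setNames(as.character(cohort$true_class),
                  names(cohort$true_class))
}
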