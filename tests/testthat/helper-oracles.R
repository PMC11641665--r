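# Independent brute-force oracles. These deliberately re-derive each
# quantity from its defining formula by direct enumeration, sharing no code
# with the package implementation.

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    # min over the suffix j >= i of m * p_(j) / j, clipped at 1
    suffix <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    q[ord[i]] <- min(1, min(suffix))
  }
  q
}

oracle_entropy <- function(assignments, classes) {
  total <- 0
  n <- length(assignments)
  for (cl in unique(assignments)) {
    members <- classes[assignments == cl]
    h <- 0
    for (k in unique(members)) {
      p <- sum(members == k) / length(members)
      h <- h - p * log2(p)
    }
    total <- total + (length(members) / n) * h
  }
  total
}

oracle_knn <- function(train, labels, test, k) {
  ids <- rownames(train)
  if (is.null(ids)) ids <- sprintf("s%06d", seq_len(nrow(train)))
  t(apply(test, 1L, function(v) {
    d <- apply(train, 1L, function(u) sum(abs(u - v)))
    nb <- order(d, ids)[seq_len(k)]
    score <- sum(labels[nb] == "tumor") / k
    c(score = score, tumor = as.numeric(score >= 0.5))
  }))
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "tumor"]
  neg <- scores[labels != "tumor"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# textbook two-group log-rank: hypergeometric expectation and variance at
# each distinct event time
oracle_logrank <- function(time, event, group) {
  g1 <- sort(unique(group))[1L]
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- o_minus_e^2 / v
  list(chi_square = chi, p = stats::pchisq(chi, 1, lower.tail = FALSE))
}

oracle_conductance <- function(edges, gene_set, all_nodes) {
  # edges: 2-column character matrix
  deg <- table(factor(c(edges[, 1], edges[, 2]), levels = all_nodes))
  cut <- 0
  for (i in seq_len(nrow(edges))) {
    a_in <- edges[i, 1] %in% gene_set
    b_in <- edges[i, 2] %in% gene_set
    if (a_in != b_in) cut <- cut + 1
  }
  vol_in <- sum(deg[gene_set])
  vol_out <- sum(deg) - vol_in
  cut / min(vol_in, vol_out)
}

# evaluate a KM step function at time t (S = 1 before the first event)
km_at <- function(km, t) {
  idx <- which(km$event_times <= t)
  if (!length(idx)) return(1)
  km$survival_prob[max(idx)]
}
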