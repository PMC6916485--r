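# Independent oracles used across the suite: exact contingency enumeration,
# brute-force Ward agglomeration, and small fixture builders.

# two-tailed Fisher p for a 2x2 table by exhaustive hypergeometric
# enumeration over all tables with the observed margins (point-probability
# definition: sum the probabilities of tables no likelier than the observed)
fisher_oracle_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-07)])
}

# same definition for a 2 x k table: enumerate every table with the observed
# margins; probability of a table is the multivariate hypergeometric mass
fisher_oracle_2xk <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); k <- ncol(tab)
  log_prob <- function(top) {
    sum(lchoose(cs, top)) - lchoose(sum(cs), rs[1])
  }
  tops <- expand.grid(lapply(cs, function(m) 0:m))
  tops <- tops[rowSums(tops) == rs[1], , drop = FALSE]
  lp <- apply(tops, 1, log_prob)
  p_obs <- log_prob(tab[1, ])
  sum(exp(lp[lp <= p_obs + 1e-07]))
}

# greedy Ward agglomeration by direct error-sum-of-squares increase;
# returns the sequence of merge costs and the final two-cluster partition
ward_oracle <- function(x) {
  ess <- function(m) sum(scale(m, scale = FALSE)^2)
  cl <- lapply(seq_len(nrow(x)), identity)
  costs <- numeric(0)
  while (length(cl) > 1) {
    best <- Inf; bi <- NULL
    for (i in 1:(length(cl) - 1)) for (j in (i + 1):length(cl)) {
      d <- ess(x[c(cl[[i]], cl[[j]]), , drop = FALSE]) -
        ess(x[cl[[i]], , drop = FALSE]) - ess(x[cl[[j]], , drop = FALSE])
      if (d < best) { best <- d; bi <- c(i, j) }
    }
    costs <- c(costs, best)
    if (length(cl) == 2) top_split <- cl
    cl[[bi[1]]] <- c(cl[[bi[1]]], cl[[bi[2]]]); cl[[bi[2]]] <- NULL
  }
  list(costs = costs, top_split = top_split)
}

# minimal valid patient table for loader tests
make_patients <- function(n = 3) {
  tibble::tibble(
    patient_id = paste0("P", seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    ancestry = rep(c("EUR", "EAS", "MENA"), length.out = n),
    homozygous = rep(c(TRUE, FALSE), length.out = n),
    allele1 = rep(c("T246M", "L123V", "E28K"), length.out = n),
    allele2 = ifelse(rep(c(TRUE, FALSE), length.out = n),
                     rep(c("T246M", "L123V", "E28K"), length.out = n),
                     "K144*"),
    aoo = seq(10, by = 2, length.out = n),
    sara = seq(12, by = 3, length.out = n),
    cd = rep(c("Y", "N"), length.out = n),
    tr = rep("Y", n),
    hypogonadism = rep("N", n)
  )
}
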