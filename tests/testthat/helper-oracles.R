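# Independent oracles frozen into the suite.

# brute-force two-way repeated-measures sums-of-squares oracle
# (cell-mean decomposition computed from first principles; stays
# independent of the aov-based implementation it checks)
rm_anova_oracle <- function(a) {
  n <- dim(a)[1]
  gm <- mean(a)
  ms <- apply(a, 1, mean); mt <- apply(a, 2, mean); me <- apply(a, 3, mean)
  mst <- apply(a, c(1, 2), mean); mse <- apply(a, c(1, 3), mean)
  mte <- apply(a, c(2, 3), mean)
  SS_t <- 2 * n * sum((mt - gm)^2)
  SS_e <- 3 * n * sum((me - gm)^2)
  SS_st <- 2 * sum((mst - outer(ms, mt, "+") + gm)^2)
  SS_se <- 3 * sum((mse - outer(ms, me, "+") + gm)^2)
  SS_te <- n * sum((mte - outer(mt, me, "+") + gm)^2)
  SS_ste <- 0
  for (i in 1:n) for (j in 1:3) for (k in 1:2)
    SS_ste <- SS_ste + (a[i, j, k] - mst[i, j] - mse[i, k] - mte[j, k] +
                          ms[i] + mt[j] + me[k] - gm)^2
  c(time = unname((SS_t / 2) / (SS_st / (2 * (n - 1)))),
    emotion = unname(SS_e / (SS_se / (n - 1))),
    time_x_emotion = unname((SS_te / 2) / (SS_ste / (2 * (n - 1)))))
}

rand_array <- function(n, seed) {
  set.seed(seed)
  array(rnorm(n * 6), c(n, 3, 2),
        dimnames = list(subject = seq_len(n),
                        retrieval = c("immediate", "12h", "24h"),
                        emotion = c("neutral", "emotional")))
}
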