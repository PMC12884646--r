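# Independent re-implementations used as oracles, plus small fixture
# builders. These deliberately share no code with the package internals.

# greedy alignment by sorting all entries and simulating row/column
# deletion (desc value, then asc row, asc col)
oracle_greedy <- function(S) {
  ent <- expand.grid(i = seq_len(nrow(S)), j = seq_len(ncol(S)))
  ent$v <- S[cbind(ent$i, ent$j)]
  ent <- ent[order(-ent$v, ent$i, ent$j), ]
  used_r <- logical(nrow(S)); used_c <- logical(ncol(S))
  total <- 0; k <- 0
  for (r in seq_len(nrow(ent))) {
    if (used_r[ent$i[r]] || used_c[ent$j[r]]) next
    total <- total + ent$v[r]; k <- k + 1
    used_r[ent$i[r]] <- TRUE; used_c[ent$j[r]] <- TRUE
    if (k == min(nrow(S), ncol(S))) break
  }
  total / k
}

# entropy-weight method evaluated step by step with explicit loops
oracle_ewm <- function(X, eps = 1e-10) {
  m <- nrow(X); n <- ncol(X)
  p <- X
  for (j in seq_len(n)) p[, j] <- X[, j] / sum(X[, j])
  p[p == 0] <- eps
  H <- numeric(n)
  for (j in seq_len(n)) {
    acc <- 0
    for (i in seq_len(m)) acc <- acc + p[i, j] * log(p[i, j])
    H[j] <- -acc / log(m)
  }
  d <- 1 - H
  list(H = H, w = d / sum(d))
}

# exact signed-rank null by enumerating all sign assignments (n <= 12)
oracle_signrank <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_plus <- signs %*% r
  list(statistic = w_obs,
       p = min(1, mean(w_plus <= w_obs) + mean(w_plus >= sum(r) - w_obs)))
}

# brute-force max-over-senses path similarity against the same taxonomy
oracle_path_sim <- function(a, b) {
  senses <- symsim:::TAXO_SENSES
  parent <- symsim:::TAXO_PARENT
  chain <- function(node) {
    out <- node
    while (node %in% names(parent)) { node <- parent[[node]]; out <- c(out, node) }
    out
  }
  sa <- senses[[a]]; sb <- senses[[b]]
  if (is.null(sa) || is.null(sb)) return(NA_real_)
  best <- NA_real_
  for (x in sa) for (y in sb) {
    ca <- chain(x); cb <- chain(y)
    common <- intersect(ca, cb)
    if (!length(common)) next
    steps <- (match(common, ca) - 1) + (match(common, cb) - 1)
    s <- 1 / (1 + min(steps))
    if (is.na(best) || s > best) best <- s
  }
  best
}

word_pool <- c("task", "play", "attention", "seat", "child", "teacher",
               "run", "climb", "talk", "listen", "organize", "lose",
               "finish", "often", "quietly", "careless", "mistake",
               "difficulty", "effort", "instruction", "question", "wait")

rand_sentence <- function(len = 5) {
  paste(sample(word_pool, len, replace = TRUE), collapse = " ")
}

rand_corpus <- function(n, seed) {
  set.seed(seed)
  symptom_corpus(text = replicate(n, rand_sentence(sample(3:8, 1))),
                 domain = sample(c("inattention", "hyperactivity_impulsivity",
                                   "non_adhd", "unknown"), n, replace = TRUE),
                 source = "random")
}

dsm5 <- load_bundled("dsm5_adhd")
dsm5_inatt <- corpus_domain(dsm5, "inattention")
dsm5_hyper <- corpus_domain(dsm5, "hyperactivity_impulsivity")
tbl5 <- load_bundled("table5_inattention")
tbl6 <- load_bundled("table6_hyperactivity")
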