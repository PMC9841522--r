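# shared fixtures and independent oracles, built in code at test time

# exhaustive K-medoids optimum: enumerate all medoid subsets
pam_oracle <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  bestm <- NULL
  for (comb in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(d[, comb, drop = FALSE], 1, min))
    if (cost < best - 1e-12) {
      best <- cost
      bestm <- comb
    }
  }
  list(cost = best, medoids = bestm)
}

# uniform random 3D rotation matrix (QR with positive diagonal, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random instance with planted cluster structure: tight within-group,
# loose between-group dissimilarities
clustered_distance_matrix <- function(n, k) {
  g <- sample(rep(seq_len(k), length.out = n))
  d <- matrix(0, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    d[a, b] <- d[b, a] <- if (g[a] == g[b]) stats::runif(1, 0, 0.15) else
      stats::runif(1, 0.6, 1)
  }
  d
}

# symmetric random distance matrix with zero diagonal
random_distance_matrix <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  d
}

# small mixed deck reused across I/O and descriptor tests
test_deck_smiles <- function() {
  c(benzene = "c1ccccc1",
    hexane = "CCCCCC",
    cpd1_like = "O=S(=O)(C)c1ccc(Nc2ncnc3sccc23)cc1",
    cpd15_like = "Cc1cc2c(Nc3ccc(S(C)(=O)=O)cc3)ncnc2s1",
    ethanol = "CCO",
    pyridine = "c1ccncc1")
}

make_test_deck <- function() {
  smi <- test_deck_smiles()
  compound_deck(names(smi), unname(smi))
}

# a molecule with 2 acceptors, 1 donor N-H and carbons: 4-aminopyrimidine-ish
# template used for pose-geometry tests
pharm_test_deck <- function(n = 4) {
  smi <- rep("O=S(=O)(C)c1ccc(Nc2ncnc3sccc23)cc1", n)
  compound_deck(sprintf("P%03d", seq_len(n)), smi)
}
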