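# Descriptor computation and the two-stage triage filters.

test_that("descriptors match hand-derived values on reference molecules", {
  deck <- make_test_deck()
  d <- compute_descriptors(deck)
  i <- match(c("benzene", "hexane", "cpd1_like"), d$id)
  # benzene: one aromatic ring, no donors, 6 heavy atoms
  expect_equal(d$aromatic_rings[i[1]], 1L)
  expect_equal(d$hbd[i[1]], 0L)
  expect_equal(d$heavy_atoms[i[1]], 6L)
  expect_equal(d$rotatable_bonds[i[1]], 0L)
  # n-hexane: 3 non-terminal C-C single bonds
  expect_equal(d$rotatable_bonds[i[2]], 3L)
  # thienopyrimidine sulfone hit: heavy atoms = 13 C + 3 N + 2 O + 2 S
  expect_equal(d$heavy_atoms[i[3]], 20L)
  expect_equal(d$aromatic_rings[i[3]], 3L)
  # descriptors are deterministic per structure
  expect_identical(d, compute_descriptors(deck))
})

test_that("amide rotors are excluded by default but configurable", {
  deck <- compound_deck("nma", "CC(=O)NC")   # N-methylacetamide
  expect_equal(compute_descriptors(deck)$rotatable_bonds, 0L)
  expect_equal(compute_descriptors(deck,
                                   include_amide_rotors = TRUE)$rotatable_bonds,
               1L)
})

test_that("stage-1 applies strict thresholds and alert reasons", {
  smis <- c(clean = "c1ccccc1",
            five_rings = grammar_smiles(1),   # placeholder, replaced below
            aldehyde = "O=Cc1ccccc1")
  smis["five_rings"] <-
    "c1ccc(-c2ccc(-c3ccc(-c4ccc(-c5ncccn5)nc4)nc3)nc2)nc1"
  deck <- compound_deck(names(smis), unname(smis))
  v <- stage1_filter(deck)
  expect_equal(nrow(v), 3)   # verdict completeness
  expect_true(v$passed[v$compound_id == "clean"])
  expect_true("aromatic_rings>4" %in%
                v$reasons[[which(v$compound_id == "five_rings")]])
  expect_true("alert:aldehyde" %in%
                v$reasons[[which(v$compound_id == "aldehyde")]])
  # passed <=> no reasons
  expect_equal(v$passed, lengths(v$reasons) == 0)

  # a compound with exactly 4 aromatic rings passes the >4 rule
  d4 <- compute_descriptors(deck)
  d4$aromatic_rings[1] <- 4L
  v4 <- stage1_filter(deck, descriptors = d4)
  expect_true(v4$passed[v4$compound_id == "clean"])
})

test_that("tightening thresholds or adding alerts never enlarges the pass set", {
  deck <- make_test_deck()
  base <- stage1_filter(deck, alerts = list())
  pass0 <- base$compound_id[base$passed]
  tight <- stage1_filter(deck, alerts = list(),
                         thresholds = list(aromatic_rings = 2,
                                           rotatable_bonds = 2, hbd = 1,
                                           clogp = 2, tpsa = 60))
  expect_true(all(tight$compound_id[tight$passed] %in% pass0))
  with_alerts <- stage1_filter(deck)
  expect_true(all(with_alerts$compound_id[with_alerts$passed] %in% pass0))
})

test_that("stage-1 filtering is idempotent on its own pass set", {
  deck <- make_test_deck()
  v1 <- stage1_filter(deck)
  deck2 <- apply_verdicts(deck, v1)
  v2 <- stage1_filter(deck2)
  expect_true(all(v2$passed))
  expect_equal(nrow(deck2), sum(v1$passed))
})

test_that("stage-2 removal combines logd and psa per the configured rule", {
  desc <- data.frame(id = c("both", "ld_only", "psa_only", "neither", "na"),
                     logd = c(6, 6, 3, 2, NA),
                     psa = c(120, 50, 120, 50, 80))
  v_and <- stage2_filter(desc)
  expect_equal(v_and$compound_id[!v_and$passed], c("both", "na"))
  expect_equal(v_and$reasons[[which(v_and$compound_id == "na")]],
               "missing_descriptor")
  v_or <- stage2_filter(desc, combine = "or")
  expect_setequal(v_or$compound_id[!v_or$passed],
                  c("both", "ld_only", "psa_only", "na"))
})

test_that("planted stage-2 quotas reproduce the pool arithmetic", {
  n <- 300; q <- 45
  set.seed(8)
  victims <- sample(n, q)
  logd <- runif(n, 0, 4.5); psa <- runif(n, 20, 95)
  logd[victims] <- runif(q, 5.1, 8); psa[victims] <- runif(q, 101, 150)
  v <- stage2_filter(data.frame(id = sprintf("p%03d", 1:n),
                                logd = logd, psa = psa))
  expect_equal(sum(v$passed), n - q)
})

test_that("alert sets validate their SMARTS and load from CSV", {
  expect_error(alert_set("bad", "x", "[[["), "SMARTS")
  tf <- tempfile(fileext = ".csv")
  write.csv(data.frame(label = "nitro_aromatic",
                       smarts = "c[N+](=O)[O-]"), tf, row.names = FALSE)
  a <- read_alert_set(tf)
  expect_s3_class(a, "alert_set")
  deck <- compound_deck(c("tnb", "benz"),
                        c("O=[N+]([O-])c1ccccc1", "c1ccccc1"))
  v <- stage1_filter(deck, alerts = list(a),
                     thresholds = stage1_thresholds())
  expect_false(v$passed[v$compound_id == "tnb"])
  expect_true(v$passed[v$compound_id == "benz"])
})
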