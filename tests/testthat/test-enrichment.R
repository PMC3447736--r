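test_that("annotation transfer keeps the best sub-cutoff hit per gene", {
  ann <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g3"),
    subject_id = c("spA", "spB", "spC", "spD", "spE"),
    evalue = c(1e-10, 1e-3, 1e-3, 1e-8, 1e-8),
    stringsAsFactors = FALSE)
  terms <- list(spA = c("T1", "T2"), spB = "T3", spC = "T4",
                spD = "T5", spE = "T6")
  tr <- transfer_annotations(ann, terms)
  expect_equal(tr$terms$g1, c("T1", "T2"))  # 1e-3 hit discarded
  expect_equal(tr$terms$g2, character(0))   # only hit fails the 1e-4 cutoff
  expect_false(tr$is_annotated[["g2"]])
  expect_equal(tr$terms$g3, "T5")           # e-value tie: smaller subject id
  expect_error(transfer_annotations(
    data.frame(gene_id = "g", subject_id = "s", evalue = -1), terms),
    "negative")
})

test_that("resampling enrichment converges to the hypergeometric tail", {
  # universe 10, set 4, term 5, overlap 4: P(X >= 4) = 5/210
  universe <- paste0("g", 1:10)
  gene_terms <- setNames(rep(list(character(0)), 10), universe)
  for (g in universe[1:5]) gene_terms[[g]] <- "T1"
  gs <- universe[c(1, 2, 3, 4)]
  res <- resampling_enrichment(gs, gene_terms, universe, R = 20000, seed = 4)
  p_exact <- choose(5, 4) * choose(5, 0) / choose(10, 4)
  expect_equal(res$overlap, 4L)
  expect_lt(abs(res$p_raw - p_exact), 0.005)
  # a term annotating the whole universe is never enriched
  for (g in universe) gene_terms[[g]] <- c(gene_terms[[g]], "T0")
  res2 <- resampling_enrichment(gs, gene_terms, universe, R = 2000, seed = 4)
  expect_equal(res2$p_raw[res2$term == "T0"], 1)
  # p floors at 1/(R+1), never zero
  expect_true(all(res2$p_raw >= 1 / 2001))
  expect_equal(nrow(resampling_enrichment(character(0), gene_terms,
                                          universe, seed = 1)), 0L)
  expect_error(resampling_enrichment(gs, gene_terms, universe, R = 2000),
               "seed")
  expect_error(resampling_enrichment("absent", gene_terms, universe,
                                     seed = 1), "subset")
})

test_that("resampling error shrinks like 3*sqrt(p(1-p)/R)", {
  set.seed(6)
  universe <- sprintf("g%03d", 1:200)
  gene_terms <- setNames(rep(list(character(0)), 200), universe)
  for (g in sample(universe, 25)) gene_terms[[g]] <- "T1"
  term_genes <- names(gene_terms)[lengths(gene_terms) > 0]
  gs <- unique(c(sample(term_genes, 10), sample(universe, 20)))
  obs <- sum(gs %in% term_genes)
  p_exact <- phyper(obs - 1, 25, 175, length(gs), lower.tail = FALSE)
  res <- resampling_enrichment(gs, gene_terms, universe, R = 20000, seed = 2)
  expect_lt(abs(res$p_raw[res$term == "T1"] - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 20000) + 2 / 20001)
})

test_that("Benjamini-Hochberg step-up matches the hand-worked example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # permutation invariance and monotonicity along the sorted order
  set.seed(10)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("the at-peak rule keeps the top quarter of the expression range", {
  m <- matrix(c(10, 20, 90, 100,
                5, 5, 5, 5,
                1, 2, 3, 4), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("PRE", "COMP", "POST", "ADULT")))
  tab <- toy_counts(m, normalized = TRUE)
  pk <- at_peak(tab, q = 0.75)
  # cutoff for g1 is 10 + 0.75 * 90 = 77.5 -> POST and ADULT only
  expect_equal(unname(pk$matrix["g1", ]), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(all(pk$matrix["g2", ]))          # constant gene: all stages
  expect_true(pk$matrix["g3", "ADULT"])        # max stage always at peak
  # every gene is at peak somewhere; scaling a gene leaves the matrix fixed
  expect_true(all(rowSums(pk$matrix) >= 1))
  m2 <- m; m2["g1", ] <- m["g1", ] * 7.3
  pk2 <- at_peak(toy_counts(m2, normalized = TRUE), q = 0.75)
  expect_equal(pk2$matrix, pk$matrix)
})

test_that("stage-family Fisher tests match closed-form hypergeometrics", {
  # universe 20, family 5, at-peak 4, all 4 in the family:
  # P = C(5,4) C(15,0) / C(20,4) = 5/4845
  universe <- sprintf("g%02d", 1:20)
  m <- matrix(1, 20, 2, dimnames = list(universe, c("PRE", "COMP")))
  m[, "COMP"] <- 50                    # every other gene peaks in COMP
  m[1:4, "PRE"] <- 100                 # exactly genes g01..g04 at peak in PRE
  tab <- toy_counts(m, normalized = TRUE)
  pk <- at_peak(tab, q = 0.75)
  fam <- universe[1:5]
  res <- stage_family_enrichment(fam, pk, "PRE")
  expect_equal(res$p_raw[res$direction == "enriched"],
               choose(5, 4) * choose(15, 0) / choose(20, 4))
  expect_error(stage_family_enrichment(character(0), pk, "PRE"), "non-empty")
})

test_that("Fisher tails agree with exhaustive enumeration and fisher.test", {
  enum_tails <- function(N, K, k, a) {
    # enumerate all tables with margins (K, N-K) x (k, N-k)
    av <- max(0, k - (N - K)):min(k, K)
    prob <- choose(K, av) * choose(N - K, k - av) / choose(N, k)
    c(enr = sum(prob[av >= a]), dep = sum(prob[av <= a]))
  }
  set.seed(19)
  for (i in 1:40) {
    N <- sample(4:15, 1)
    K <- sample(1:(N - 1), 1)          # at-peak count
    k <- sample(1:(N - 1), 1)          # family size
    a <- sample(max(0, k - (N - K)):min(k, K), 1)
    universe <- sprintf("g%02d", 1:N)
    pk <- structure(list(
      matrix = matrix(universe %in% universe[seq_len(K)], ncol = 1,
                      dimnames = list(universe, "S1")),
      universe = universe, q = 0.75), class = "at_peak_matrix")
    fam <- c(universe[seq_len(a)],
             universe[K + seq_len(k - a)])        # a at-peak, k-a not
    res <- stage_family_enrichment(fam, pk, "S1")
    et <- enum_tails(N, K, k, a)
    expect_equal(res$p_raw[res$direction == "enriched"], unname(et["enr"]))
    expect_equal(res$p_raw[res$direction == "depleted"], unname(et["dep"]))
    # independent library cross-check
    tabm <- matrix(c(a, k - a, K - a, N - K - (k - a)), 2)
    expect_equal(res$p_raw[res$direction == "enriched"],
                 fisher.test(tabm, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("family at-peak rates equal to background are not enriched", {
  universe <- sprintf("g%02d", 1:20)
  m <- matrix(100, 20, 2, dimnames = list(universe, c("PRE", "COMP")))
  m[, "PRE"] <- 1
  m[c(1, 2, 6, 7, 11, 12, 16, 17), "PRE"] <- 100   # 40% at peak in PRE
  m[c(1, 2, 6, 7, 11, 12, 16, 17), "COMP"] <- 1
  pk <- at_peak(toy_counts(m, normalized = TRUE), q = 0.75)
  fam <- universe[c(1, 2, 3, 4, 5)]                # 2/5 at peak = background
  res <- stage_family_enrichment(fam, pk, "PRE")
  expect_gte(res$p_raw[res$direction == "enriched"], 0.5)
})
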