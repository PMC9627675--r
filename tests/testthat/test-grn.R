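test_that("signaling scores are absolute row/column sums", {
  A <- matrix(c(0, 2, -3, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("g1", "g2")))
  sc <- signaling_scores(A)
  expect_equal(sc$incoming, c(2, 3))
  expect_equal(sc$outgoing, c(3, 2))
  expect_equal(sc$total, c(5, 5))
  z <- signaling_scores(matrix(0, 2, 2))
  expect_true(all(z$incoming == 0 & z$outgoing == 0 & z$total == 0))
})

test_that("total incoming equals total outgoing weight (conservation)", {
  set.seed(9)
  for (rep in 1:5) {
    A <- matrix(rnorm(25), 5, 5); diag(A) <- 0
    sc <- signaling_scores(A)
    expect_equal(sum(sc$incoming), sum(sc$outgoing))
    expect_equal(sum(sc$incoming), sum(abs(A)))
  }
})

test_that("permuting gene order permutes scores identically", {
  set.seed(10)
  A <- matrix(rnorm(16), 4, 4); diag(A) <- 0
  rownames(A) <- colnames(A) <- paste0("g", 1:4)
  p <- c(3, 1, 4, 2)
  sc <- signaling_scores(A)
  scp <- signaling_scores(A[p, p])
  expect_equal(scp$incoming, sc$incoming[p])
  expect_equal(scp$outgoing, sc$outgoing[p])
})

test_that("quantile threshold keeps the expected edges", {
  A <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  A[1, 2] <- 0.1; A[2, 1] <- -0.5; A[1, 3] <- 1.0; A[3, 1] <- 2.0
  g0 <- quantile_grn(A, q = 0)
  expect_equal(igraph::ecount(g0), 4)
  # median of {0.1, 0.5, 1, 2} = 0.75 -> keep |w| in {1, 2}
  g5 <- quantile_grn(A, q = 0.5)
  expect_equal(sort(abs(igraph::E(g5)$weight)), c(1, 2))
  g99 <- quantile_grn(A, q = 0.99)
  expect_equal(abs(igraph::E(g99)$weight), 2)
  expect_equal(igraph::E(g99)$sign, 1)
  expect_warning(quantile_grn(matrix(0, 2, 2)), "all-zero")
})

test_that("edge sets shrink monotonically in the threshold quantile", {
  set.seed(11)
  A <- matrix(rnorm(36), 6, 6); diag(A) <- 0
  rownames(A) <- colnames(A) <- paste0("g", 1:6)
  key <- function(g) apply(igraph::as_edgelist(g), 1, paste, collapse = ">")
  prev <- key(quantile_grn(A, 0))
  for (q in c(0.3, 0.6, 0.9)) {
    cur <- key(quantile_grn(A, q))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("edges point regulator -> target", {
  A <- matrix(0, 2, 2, dimnames = list(c("tgt", "reg"), c("tgt", "reg")))
  A["tgt", "reg"] <- 1.5   # reg regulates tgt
  g <- quantile_grn(A, 0)
  el <- igraph::as_edgelist(g)
  expect_equal(el[1, ], c("reg", "tgt"))
})

test_that("betweenness reflects path topology on the thresholded graph", {
  A <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  A["b", "a"] <- 1; A["c", "b"] <- 1   # a -> b -> c
  b <- grn_betweenness(quantile_grn(A, 0))
  expect_gt(b[["b"]], 0)
  expect_equal(unname(b[c("a", "c")]), c(0, 0))
  # star hub: hub regulates all leaves; hub centrality >= any leaf
  A2 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  A2[2:4, 1] <- 1; A2[1, 2:4] <- 0.5
  b2 <- grn_betweenness(quantile_grn(A2, 0))
  expect_true(all(b2[[1]] >= b2[-1]))
  g_empty <- suppressWarnings(quantile_grn(diag(0, 2) + 0, 0))
  expect_warning(b0 <- grn_betweenness(g_empty), "empty")
  expect_true(all(b0 == 0))
})

test_that("cross-state variability measures rank dispersion correctly", {
  mk_model <- function(A, state) {
    rownames(A) <- colnames(A) <- paste0("g", seq_len(nrow(A)))
    structure(list(A = A, state = state), class = "state_linear_model")
  }
  # gene g2 receives (1, 3, 5) across states -> range 4, sd 2
  As <- lapply(c(1, 3, 5), function(w) {
    A <- matrix(0, 2, 2); A[2, 1] <- w; A
  })
  fit <- structure(list(models = mapply(mk_model, As, c("s1", "s2", "s3"),
                                        SIMPLIFY = FALSE),
                        gene_names = c("g1", "g2")),
                   class = "splice_fit")
  v <- variability_across_states(fit, metric = "incoming", measure = "range")
  expect_equal(v$variability[v$gene == "g2"], 4)
  expect_equal(v$variability[v$gene == "g1"], 0)
  vs <- variability_across_states(fit, metric = "incoming", measure = "sd")
  expect_equal(vs$variability[vs$gene == "g2"], 2)
  expect_error(variability_across_states(fit, metric = "nope"),
               "arg")
})

test_that("iqr is less outlier-driven than range", {
  vals <- c(1, 2, 3, 4, 100)
  expect_equal(diff(range(vals)), 99)
  expect_lt(stats::IQR(vals), 99)
})

test_that("differential and conserved interactions rank edge changes", {
  A <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("g1", "g2")))
  B <- A; B[1, 2] <- 5
  d <- differential_interactions(A, B)
  expect_equal(d$change[1], 5)
  expect_identical(d[1, c("regulator", "target")],
                   data.frame(regulator = "g2", target = "g1"))
  same <- differential_interactions(A, A)
  expect_true(all(same$change == 0))
  Aa <- A; Aa[2, 1] <- 2
  Ab <- A; Ab[2, 1] <- -2
  expect_equal(differential_interactions(Aa, Ab)$change[1], 4)
  cons <- conserved_interactions(Aa, Ab)
  expect_equal(nrow(cons), 1L)  # only edges nonzero somewhere count
  A3 <- matrix(0, 3, 3)
  expect_error(differential_interactions(A, A3), "gene set")
})

test_that("AUROC matches exhaustive pair counting and pROC", {
  scores <- c(0.9, 0.8, 0.2, 0.1)
  labels <- c(TRUE, FALSE, TRUE, FALSE)
  # exhaustive positive-negative pair comparison
  pos <- scores[labels]; neg <- scores[!labels]
  manual <- mean(outer(pos, neg, function(p, q)
    (p > q) + 0.5 * (p == q)))
  expect_equal(auroc(scores, labels), manual)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<")))
  expect_equal(auroc(scores, labels), as.numeric(ref))
  set.seed(12)
  s2 <- rnorm(50); l2 <- runif(50) < 0.4
  ref2 <- suppressMessages(pROC::auc(pROC::roc(l2, s2, direction = "<")))
  expect_equal(auroc(s2, l2), as.numeric(ref2))
  expect_error(auroc(s2, rep(TRUE, 50)), "degenerate")
})

test_that("AUPRC equals the threshold-enumeration oracle", {
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  labels <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  # enumerate descending thresholds, accumulate precision at recall steps
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in ths) {
    sel <- scores >= t
    prec <- mean(labels[sel])
    rec <- sum(labels[sel]) / sum(labels)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  expect_equal(auprc(scores, labels), area)
  expect_equal(auprc(rep(1, 5), labels), mean(labels))  # constant scores
  expect_equal(auprc(labels + 0, labels), 1)            # perfect separation
})

test_that("GRN similarity is 1 on self and prevalence for flat scores", {
  set.seed(13)
  A <- matrix(rnorm(25), 5, 5); diag(A) <- 0
  rownames(A) <- colnames(A) <- paste0("g", 1:5)
  for (q in c(0.5, 0.9)) {
    s <- grn_similarity(A, A, q_truth = q)
    expect_equal(s$auroc, 1)
    expect_equal(s$auprc, 1)
  }
  flat <- matrix(1, 5, 5); diag(flat) <- 0
  dimnames(flat) <- dimnames(A)
  s <- grn_similarity(flat, A, q_truth = 0.8)
  off <- row(A) != col(A)
  prev <- mean(abs(A)[off] >= quantile(abs(A)[off], 0.8))
  expect_equal(s$auprc, prev)
  expect_error(grn_similarity(A, 0 * A), "all zero")
})

test_that("similarity matrix has a unit diagonal", {
  set.seed(14)
  mk <- function(state) {
    A <- matrix(rnorm(16), 4, 4); diag(A) <- 0
    rownames(A) <- colnames(A) <- paste0("g", 1:4)
    structure(list(A = A, state = state), class = "state_linear_model")
  }
  fit <- structure(list(models = list(s1 = mk("s1"), s2 = mk("s2")),
                        gene_names = paste0("g", 1:4)),
                   class = "splice_fit")
  M <- grn_similarity_matrix(fit, q_truth = 0.5)
  expect_equal(unname(diag(M)), c(1, 1))
  expect_true(all(M >= 0 & M <= 1))
})

test_that("core GRN is an induced subgraph tagged by category", {
  set.seed(15)
  A <- matrix(rnorm(36), 6, 6); diag(A) <- 0
  rownames(A) <- colnames(A) <- paste0("g", 1:6)
  model <- structure(list(A = A, state = "s"), class = "state_linear_model")
  ta <- structure(list(IS = stats::setNames(c(1, 0.8, 0.1, 0, 0, 0),
                                            paste0("g", 1:6)),
                       raw = stats::setNames(c(1, 0.8, 0.1, 0, 0, 0),
                                             paste0("g", 1:6))),
                  class = "transition_analysis")
  deg <- data.frame(gene = c("g5", "g6", "g1"))
  g <- core_grn(model, ta, deg, n_deg = 2, n_tg = 2, q = 0)
  expect_setequal(igraph::V(g)$name, c("g1", "g2", "g5", "g6"))
  full <- quantile_grn(model, 0)
  el <- igraph::as_edgelist(g); elf <- igraph::as_edgelist(full)
  expect_true(all(paste(el[, 1], el[, 2]) %in% paste(elf[, 1], elf[, 2])))
  only_tg <- core_grn(model, ta, deg, n_deg = 0, n_tg = 2, q = 0)
  expect_setequal(igraph::V(only_tg)$name, c("g1", "g2"))
  expect_true(all(igraph::V(only_tg)$category == "TG"))
  both <- core_grn(model, ta, data.frame(gene = "g1"), n_deg = 1, n_tg = 1,
                   q = 0)
  expect_identical(igraph::vertex_attr(both, "category", "g1"), "DEG+TG")
})

test_that("DEG fallback ranks state-enriched genes first", {
  U <- matrix(1, 6, 2)
  S <- cbind(c(9, 9, 9, 1, 1, 1), c(1, 1, 1, 1, 1, 1))
  ds <- splice_dataset(U, S, rep(c("hi", "lo"), each = 3),
                       gene_names = c("up", "flat"))
  tab <- deg_scores(ds, "hi")
  expect_identical(tab$gene[1], "up")
  expect_equal(tab$log2fc[tab$gene == "flat"], 0)
})

test_that("GRN export writes GraphML and an edge table", {
  A <- matrix(c(0, 1, -2, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("g1", "g2")))
  dir <- withr::local_tempdir()
  write_grn(quantile_grn(A, 0), file.path(dir, "net"))
  expect_true(file.exists(file.path(dir, "net.graphml")))
  tab <- read.delim(file.path(dir, "net_edges.tsv"))
  expect_setequal(names(tab), c("regulator", "target", "weight", "sign"))
  expect_equal(nrow(tab), 2L)
})
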