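# Network forward/backward correctness, invariances, metrics, training.

tiny_config <- function(seed = 3) {
  dta_config(d_drug = 8, d_prot = 8, att_dim = 6, hidden = 5,
             kernels = c(2, 2, 3), theta_d = 50, theta_p = 60,
             epochs = 1, batch_size = 4, lr = 1e-3, seed = seed)
}

tiny_inputs <- function() {
  g <- featurize_molecule("CC(=O)NC(=O)CO")[[1]]
  p <- encode_protein("MKTAYIAKQRWHKCWLVHSER")
  list(g = g, p = p)
}

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_config()
  model <- dta_init(cfg)
  inp <- tiny_inputs()
  gi <- herbmet:::.graph_input(inp$g)
  kernels <- as.integer(cfg$kernels)
  y <- 1

  res <- herbmet:::.cpp_dta_batch_grad(list(gi), list(inp$p), y, 1,
                                       model$params, kernels)
  loss_at <- function(params) {
    f <- herbmet:::.cpp_dta_forward(gi$M, gi$A, inp$p, params, kernels)
    p <- min(max(f$p, 1e-12), 1 - 1e-12)
    -(y * log(p) + (1 - y) * log(1 - p))
  }
  h <- 1e-5
  check_entry <- function(name, i, sub = NULL) {
    pp <- model$params
    get <- function(x) if (is.null(sub)) x[[name]] else x[[name]][[sub]]
    set <- function(x, v) {
      if (is.null(sub)) x[[name]] <- v else x[[name]][[sub]] <- v
      x
    }
    v <- get(pp); v[i] <- v[i] + h
    up <- loss_at(set(pp, v))
    v[i] <- v[i] - 2 * h
    dn <- loss_at(set(pp, v))
    fd <- (up - dn) / (2 * h)
    an <- get(res$grads)[i]
    expect_equal(an, fd, tolerance = 1e-4)
  }
  set.seed(99)
  for (nm in c("W0", "Ep", "U", "V", "Wc1", "wc2")) {
    for (i in sample(length(model$params[[nm]]), 4)) check_entry(nm, i)
  }
  for (l in 1:3) {
    check_entry("Wg", sample(length(model$params$Wg[[l]]), 1), sub = l)
    check_entry("Cw", sample(length(model$params$Cw[[l]]), 1), sub = l)
    check_entry("Cb", sample(length(model$params$Cb[[l]]), 1), sub = l)
  }
  for (i in sample(length(model$params$q), 3)) check_entry("q", i)
  check_entry("bc1", 1)
  check_entry("bc2", 1)
})

test_that("output is a probability, attention covers real pairs, padding never matters", {
  cfg <- tiny_config()
  model <- dta_init(cfg)
  inp <- tiny_inputs()
  f <- herbmet:::.dta_forward(model$params, inp$g, inp$p, cfg)
  expect_gte(f$p, 0); expect_lte(f$p, 1)
  L_eff <- length(inp$p) - sum(cfg$kernels - 1)
  expect_equal(dim(f$attention), c(inp$g$n_real, L_eff))
  expect_equal(sum(f$attention), 1, tolerance = 1e-12)
  # virtual-node padding leaves the probability bit-identical
  padded <- pad_graph(inp$g, 30)
  f_pad <- herbmet:::.dta_forward(model$params, padded, inp$p, cfg)
  expect_identical(f$p, f_pad$p)
})

test_that("the network is invariant to atom reindexing", {
  cfg <- tiny_config()
  model <- dta_init(cfg)
  inp <- tiny_inputs()
  f0 <- herbmet:::.dta_forward(model$params, inp$g, inp$p, cfg)
  set.seed(8)
  for (rep in 1:5) {
    perm <- sample(inp$g$n_real)
    g2 <- inp$g
    g2$features <- g2$features[perm, , drop = FALSE]
    g2$adj_norm <- g2$adj_norm[perm, perm, drop = FALSE]
    f2 <- herbmet:::.dta_forward(model$params, g2, inp$p, cfg)
    expect_equal(f2$p, f0$p, tolerance = 1e-12)
  }
})

test_that("zero classifier weights give exactly sigmoid(bias)", {
  cfg <- tiny_config()
  model <- dta_init(cfg)
  model$params$wc2[] <- 0
  model$params$bc2 <- 0.7
  inp <- tiny_inputs()
  f <- herbmet:::.dta_forward(model$params, inp$g, inp$p, cfg)
  expect_equal(f$p, 1 / (1 + exp(-0.7)), tolerance = 1e-12)
})

test_that("zero learning rate freezes the loss trace; fixed seed reproduces it", {
  sim <- simulate_dta(40, balance = 0.3, label_noise = 0, seed = 13,
                      protein_length = c(40, 60))
  cfg <- dta_config(d_drug = 8, d_prot = 8, att_dim = 6, hidden = 5,
                    kernels = c(2, 2, 3), theta_p = 60, epochs = 3,
                    batch_size = 8, lr = 0, seed = 3)
  m <- train_dta(sim$records, cfg)
  expect_equal(length(unique(round(m$loss_trace, 12))), 1)
  cfg$lr <- 1e-3
  m1 <- train_dta(sim$records, cfg)
  m2 <- train_dta(sim$records, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$loss_trace, m2$loss_trace)
  # training on a single class is refused
  one_class <- sim$records[sim$records$label == 0, ]
  expect_error(train_dta(one_class, cfg), "both classes")
})

test_that("threshold-free and thresholded metrics equal brute-force oracles", {
  # hand-made six-point list
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0)
  expect_equal(auroc(scores, labels), oracle_auroc(scores, labels), tolerance = 1e-12)
  expect_equal(auprc(scores, labels), oracle_auprc(scores, labels), tolerance = 1e-12)
  pt <- f1_point(scores, labels); opt <- oracle_f1(scores, labels)
  expect_equal(pt$f1, opt$f1, tolerance = 1e-12)
  expect_equal(pt$sensitivity, opt$sensitivity, tolerance = 1e-12)

  # perfect scores
  expect_equal(auroc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(auprc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(f1_point(c(0, 0, 1, 1), c(0, 0, 1, 1))$f1, 1)

  # random lists of every size up to 10, with ties forced via a coarse grid
  set.seed(77)
  for (n in 2:10) {
    for (rep in 1:20) {
      labels <- sample(0:1, n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
      expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                   tolerance = 1e-9)
      expect_equal(auprc(scores, labels), oracle_auprc(scores, labels),
                   tolerance = 1e-9)
      a <- f1_point(scores, labels); b <- oracle_f1(scores, labels)
      expect_equal(a$f1, b$f1, tolerance = 1e-9)
      expect_equal(a$threshold, b$threshold, tolerance = 1e-9)
      expect_equal(a$specificity, b$specificity, tolerance = 1e-9)
      expect_equal(a$accuracy, b$accuracy, tolerance = 1e-9)
    }
  }
  expect_error(auroc(c(1, 2), c(1, 1)), "single class")

  # random scores at prevalence p: AUPRC approaches p
  set.seed(123)
  n <- 4000; p <- 0.13
  labels <- rbinom(n, 1, p)
  scores <- runif(n)
  expect_lt(abs(auprc(scores, labels) - mean(labels)), 0.03)
})

test_that("rank_candidates scores all pairs, sorted, and top-k agrees with the full sort", {
  sim <- simulate_dta(30, balance = 0.3, label_noise = 0, seed = 20,
                      protein_length = c(40, 60))
  cfg <- dta_config(d_drug = 8, d_prot = 8, att_dim = 6, hidden = 5,
                    kernels = c(2, 2, 3), theta_p = 60, epochs = 1,
                    batch_size = 8, lr = 1e-3, seed = 3)
  m <- train_dta(sim$records, cfg)
  mols <- data.frame(name = paste0("m", 1:4),
                     smiles = sim$records$smiles[1:4])
  targs <- data.frame(target_id = c("AMPK", "SIRT6"),
                      sequence = sim$records$sequence[5:6])
  rk <- rank_candidates(m, mols, targs)
  expect_equal(nrow(rk), 8)
  expect_true(all(diff(rk$score) <= 0))
  expect_true(all(rk$score >= 0 & rk$score <= 1))
  top3 <- rank_candidates(m, mols, targs, top_k = 3)
  expect_identical(top3, rk[1:3, ])
  # deterministic given a fixed model
  expect_identical(rk, rank_candidates(m, mols, targs))
})

test_that("rank-based AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  labels <- rbinom(300, 1, 0.3)
  scores <- runif(300) + 0.4 * labels
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
})
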