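# --- collinearity screen ----------------------------------------------------

fake_pheno <- function(n = 60, seed = 101) {
  withr::with_seed(seed, {
    ph <- as.data.frame(matrix(rnorm(n * 9), n, 9))
    names(ph) <- predictor_names()
    ph$pld <- rnorm(n)
    ph$settlement_date <- ph$hatch_date + 0.2 * rnorm(n) # r > 0.8
    ph
  })
}

test_that("the later member of a collinear pair is dropped", {
  ph <- fake_pheno()
  pm <- drop_correlated_predictors(ph)
  expect_false("settlement_date" %in% pm$predictors)
  expect_true("hatch_date" %in% pm$predictors)
  expect_equal(pm$dropped$predictor, "settlement_date")
  expect_gt(abs(pm$dropped$r), 0.8)
  expect_equal(unname(colMeans(pm$matrix)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(pm$matrix, 2, sd)), rep(1, 8), tolerance = 1e-12)
})

test_that("orthogonal predictors are all kept", {
  withr::with_seed(7, {
    ph <- as.data.frame(matrix(rnorm(2000 * 9), 2000, 9))
    names(ph) <- predictor_names()
    pm <- drop_correlated_predictors(ph)
    expect_equal(nrow(pm$dropped), 0L)
    expect_length(pm$predictors, 9L)
  })
})

test_that("three mutually correlated predictors keep only the canonical first", {
  withr::with_seed(8, {
    base <- rnorm(400)
    ph <- as.data.frame(matrix(rnorm(400 * 9), 400, 9))
    names(ph) <- predictor_names()
    ph$hatch_date <- base + 0.1 * rnorm(400)
    ph$pld <- base + 0.1 * rnorm(400)
    ph$sst <- base + 0.1 * rnorm(400)
    pm <- drop_correlated_predictors(ph)
    expect_true("hatch_date" %in% pm$predictors)
    expect_false(any(c("pld", "sst") %in% pm$predictors))
    expect_equal(nrow(pm$dropped), 2L)
  })
})

test_that("a constant predictor is an error naming it", {
  ph <- fake_pheno()
  ph$grpld <- 3
  expect_error(drop_correlated_predictors(ph), "grpld")
})

# --- imputation -------------------------------------------------------------

test_that("missing calls become the per-SNP mode with ties to the lower code", {
  m <- matrix(c(0L, 0L, 1L, NA), 4, 1)
  expect_equal(impute_missing_genotypes(m)[4, 1], 0L)
  m2 <- matrix(c(0L, 0L, 2L, 2L, NA), 5, 1)
  expect_equal(impute_missing_genotypes(m2)[5, 1], 0L) # tie -> lower code
  m3 <- matrix(c(1L, 2L, 2L, NA), 4, 1)
  expect_equal(impute_missing_genotypes(m3)[4, 1], 2L)
  full <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  expect_identical(impute_missing_genotypes(full), full)
})

test_that("an all-missing SNP uses the fallback or errors", {
  m <- matrix(c(NA, NA, 0L, 1L), 2, 2,
              dimnames = list(NULL, c("s1", "s2")))
  expect_error(impute_missing_genotypes(m), "s1")
  out <- impute_missing_genotypes(m, fallback = c(s1 = 2L, s2 = 0L))
  expect_equal(out[, "s1"], c(2L, 2L))
})

# --- RDA fit ----------------------------------------------------------------

test_that("a perfectly predicted SNP loads on a single constrained axis", {
  withr::with_seed(31, {
    x <- rnorm(50)
    Y <- cbind(snp = 1 + 0.5 * x)
    fit <- rda_fit(Y, cbind(x = x))
    expect_length(fit$eigenvalues, 1L)
    expect_equal(fit$constrained_inertia, fit$total_inertia, tolerance = 1e-10)
    expect_equal(abs(unname(fit$loadings[1, 1])), 1, tolerance = 1e-10)
  })
})

test_that("axes and eigenvalues match the brute-force projection oracle", {
  withr::with_seed(32, {
    for (rep in 1:5) {
      n <- sample(10:30, 1)
      L <- sample(8:50, 1)
      p <- sample(2:4, 1)
      Y <- matrix(rbinom(n * L, 2, 0.4) + rnorm(n * L, sd = 0.01), n, L)
      X <- matrix(rnorm(n * p), n, p)
      fit <- rda_fit(Y, X)
      orc <- rda_oracle(Y, X)
      k <- min(length(fit$eigenvalues), length(orc$eigenvalues))
      expect_equal(fit$eigenvalues[1:k], orc$eigenvalues[1:k],
                   tolerance = 1e-8, ignore_attr = TRUE)
      for (j in 1:k) {
        dot <- abs(sum(fit$loadings[, j] * orc$loadings[, j]))
        expect_equal(dot, 1, tolerance = 1e-8)
      }
    }
  })
})

test_that("constrained inertia never exceeds total inertia", {
  withr::with_seed(33, {
    for (rep in 1:5) {
      Y <- matrix(rbinom(200 * 30, 2, 0.3), 200, 30)
      X <- matrix(rnorm(200 * 4), 200, 4)
      fit <- rda_fit(Y, X)
      expect_lte(fit$constrained_inertia, fit$total_inertia + 1e-10)
    }
  })
})

test_that("null genotypes give a constrained fraction near p/(n-1)", {
  withr::with_seed(34, {
    fracs <- replicate(10, {
      n <- 200; p <- 4
      Y <- matrix(rbinom(n * 300, 2, 0.4), n, 300)
      X <- matrix(rnorm(n * p), n, p)
      fit <- rda_fit(Y, X)
      fit$constrained_inertia / fit$total_inertia
    })
    expect_equal(mean(fracs), 4 / 199, tolerance = 0.15)
  })
})

test_that("axes are equivariant to predictor column order", {
  withr::with_seed(35, {
    Y <- matrix(rbinom(40 * 20, 2, 0.4), 40, 20)
    X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
    f1 <- rda_fit(Y, X)
    f2 <- rda_fit(Y, X[, c(3, 1, 2)])
    expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-10)
    for (j in seq_along(f1$eigenvalues))
      expect_equal(abs(sum(f1$loadings[, j] * f2$loadings[, j])), 1,
                   tolerance = 1e-8)
  })
})

test_that("duplicated predictors raise a rank-deficiency error", {
  withr::with_seed(36, {
    Y <- matrix(rnorm(60), 20, 3)
    x <- rnorm(20)
    expect_error(rda_fit(Y, cbind(a = x, b = x)), "rank")
  })
})

# --- outlier rule -----------------------------------------------------------

fake_fit <- function(loadings) {
  structure(list(eigenvalues = rep(1, ncol(loadings)), loadings = loadings),
            class = "rda_fit")
}

test_that("equal loadings on an axis flag nothing", {
  l <- matrix(0.3, 100, 1, dimnames = list(sprintf("s%d", 1:100), "RDA1"))
  expect_equal(nrow(detect_outliers(fake_fit(l))), 0L)
})

test_that("a planted extreme loading is flagged", {
  withr::with_seed(41, {
    l <- matrix(rnorm(500, sd = 0.1), 500, 1,
                dimnames = list(sprintf("s%d", 1:500), "RDA1"))
    l[77, 1] <- mean(l[-77, 1]) + 5 * sd(l[-77, 1])
    out <- detect_outliers(fake_fit(l))
    expect_true("s77" %in% out$snp_id)
  })
})

test_that("standard-normal loadings are flagged at close to the 3-SD tail rate", {
  withr::with_seed(42, {
    l <- matrix(rnorm(1e5), ncol = 1,
                dimnames = list(sprintf("s%d", 1:1e5), "RDA1"))
    out <- detect_outliers(fake_fit(l))
    frac <- nrow(out) / 1e5
    expect_equal(frac, 2 * pnorm(-3), tolerance = 0.0005 / 0.0027)
  })
})

test_that("the union over axes attributes each SNP to its first flagging axis", {
  l <- matrix(rnorm(400, sd = 0.05), 200, 2,
              dimnames = list(sprintf("s%d", 1:200), c("RDA1", "RDA2")))
  l[1, 1] <- 10; l[1, 2] <- 10; l[2, 2] <- 10
  out <- detect_outliers(fake_fit(l))
  expect_equal(out$axis[out$snp_id == "s1"], "RDA1")
  expect_equal(out$axis[out$snp_id == "s2"], "RDA2")
  expect_equal(sum(out$snp_id == "s1"), 1L)
})

# --- predictor assignment ---------------------------------------------------

test_that("assignment picks the strongest predictor with its sign", {
  withr::with_seed(51, {
    n <- 80
    ph <- as.data.frame(matrix(rnorm(n * 9), n, 9))
    names(ph) <- predictor_names()
    pm <- drop_correlated_predictors(ph)
    g_sst <- as.numeric(scale(ph$sst))
    g_neg <- -as.numeric(scale(ph$hatch_date))
    G <- cbind(snp_sst = g_sst, snp_neg = g_neg)
    res <- assign_predictor(G, pm)
    expect_equal(res$predictor[res$snp_id == "snp_sst"], "sst")
    expect_equal(res$r[res$snp_id == "snp_sst"], 1, tolerance = 1e-12)
    expect_equal(res$predictor[res$snp_id == "snp_neg"], "hatch_date")
    expect_equal(res$sign[res$snp_id == "snp_neg"], -1L)
  })
})

test_that("an exact |r| tie goes to the earlier canonical predictor", {
  withr::with_seed(52, {
    n <- 64
    a <- rnorm(n); b <- rnorm(n)
    a <- as.numeric(scale(a)); b <- as.numeric(scale(residuals(lm(b ~ a))))
    g <- 0.6 * a + 0.6 * b # equally correlated with both
    ph <- as.data.frame(matrix(rnorm(n * 9), n, 9))
    names(ph) <- predictor_names()
    ph$grpld <- a # earlier in canonical order than sst
    ph$sst <- b
    pm <- drop_correlated_predictors(ph)
    res <- assign_predictor(cbind(snp_tie = g), pm)
    r_g <- cor(g, a); r_s <- cor(g, b)
    expect_equal(abs(r_g), abs(r_s), tolerance = 1e-12)
    expect_equal(res$predictor, "grpld")
  })
})

test_that("zero-variance SNPs are dropped from assignment with a warning", {
  ph <- fake_pheno(n = 30)
  pm <- drop_correlated_predictors(ph)
  G <- cbind(flat = rep(1, 30), ok = rnorm(30))
  expect_warning(res <- assign_predictor(G, pm), "zero-variance")
  expect_equal(res$snp_id, "ok")
})
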