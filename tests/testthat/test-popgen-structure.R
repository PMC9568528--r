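# --- Weir-Cockerham F_ST ----------------------------------------------------

test_that("theta is near zero for identical genotype distributions", {
  g <- counts_to_geno(c(25, 50, 25))
  res <- weir_cockerham_fst(g, g)
  expect_lte(res$theta, 0)
  expect_lt(abs(res$theta), 0.01)
})

test_that("theta is exactly 1 for a fixed difference", {
  ga <- matrix(0L, 20, 1)
  gb <- matrix(2L, 20, 1)
  expect_equal(weir_cockerham_fst(ga, gb)$theta, 1.0)
})

test_that("toy counts match the independently coded 1984 worked computation", {
  cases <- list(list(a = c(10, 10, 0), b = c(0, 10, 10)),
                list(a = c(30, 10, 5), b = c(5, 20, 30)),
                list(a = c(12, 6, 2), b = c(8, 9, 3)))
  for (cs in cases) {
    res <- weir_cockerham_fst(counts_to_geno(cs$a), counts_to_geno(cs$b))
    expect_equal(res$theta, wc_fst_oracle(cs$a, cs$b), tolerance = 1e-10)
  }
  # frozen value of the first toy, computed by hand from the components:
  # a = 2.3125/19, b = -1.125/19, c = 4.75/19 -> theta = 2.3125/5.9375
  res <- weir_cockerham_fst(counts_to_geno(c(10, 10, 0)),
                            counts_to_geno(c(0, 10, 10)))
  expect_equal(res$theta, 2.3125 / 5.9375, tolerance = 1e-12)
})

test_that("theta is invariant to allele-label swap", {
  withr::with_seed(5, {
    ga <- matrix(rbinom(200, 2, 0.3), 20, 10)
    gb <- matrix(rbinom(200, 2, 0.6), 20, 10)
    t1 <- weir_cockerham_fst(ga, gb)$theta
    t2 <- weir_cockerham_fst(2L - ga, 2L - gb)$theta
    expect_equal(t1, t2, tolerance = 1e-12)
  })
})

test_that("missing calls are handled and no shared locus is an error", {
  ga <- matrix(c(0L, 1L, NA, 2L), 4, 1)
  gb <- matrix(c(1L, NA, 0L, 1L), 4, 1)
  expect_s3_class(weir_cockerham_fst(ga, gb), "fst_result")
  expect_error(weir_cockerham_fst(matrix(0L, 4, 1), matrix(0L, 4, 1)),
               "polymorphic")
})

test_that("permutation p is 1 for identical groups and minimal for fixed difference", {
  g <- counts_to_geno(c(8, 8, 4))
  expect_equal(fst_permutation_test(g, g, n_perm = 199, seed = 3)$p_value, 1.0)
  ga <- matrix(0L, 20, 1)
  gb <- matrix(2L, 20, 1)
  res <- fst_permutation_test(ga, gb, n_perm = 999, seed = 4)
  expect_equal(res$p_value, 1 / 1000)
})

test_that("haplotype F_ST agrees with SNP F_ST on single-SNP tags", {
  withr::with_seed(9, {
    n <- 30
    calls <- matrix(rbinom(n * 8, 2, runif(8, 0.2, 0.8)), n, 8, byrow = TRUE)
    storage.mode(calls) <- "integer"
    colnames(calls) <- sprintf("t%d_snp1", 1:8)
    rownames(calls) <- sprintf("i%02d", 1:n)
    grp <- rep(c("A", "B"), each = 15)
    co <- make_cohort(calls, NULL, grp, rep("settler", n))
    haps <- collapse_haplotypes(co)$haplotypes
    t_hap <- haplotype_fst(haps, setNames(grp, rownames(calls)))$theta
    t_snp <- weir_cockerham_fst(calls[1:15, ], calls[16:30, ])$theta
    expect_equal(t_hap, t_snp, tolerance = 1e-10)
  })
})

# --- PERMANOVA --------------------------------------------------------------

test_that("univariate Euclidean pseudo-F equals the classical ANOVA F", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      y <- rnorm(24)
      g <- factor(sample(rep(c("a", "b", "c"), 8)))
      res <- permanova(y ~ g, data.frame(y = y, g = g), n_perm = 0)
      f_classic <- anova(lm(y ~ g))["g", "F value"]
      expect_equal(res$table$pseudo_F[1], f_classic, tolerance = 1e-12)
    }
  })
})

test_that("sequential two-factor SS match Type-I ANOVA on univariate data", {
  withr::with_seed(12, {
    y <- rnorm(8)
    A <- factor(rep(c("x", "y"), 4))
    B <- factor(rep(c("u", "v"), each = 4))
    res <- permanova(y ~ A * B, data.frame(y = y, A = A, B = B), n_perm = 0)
    ref <- anova(lm(y ~ A * B))
    expect_equal(res$table$ss[1:3],
                 ref[c("A", "B", "A:B"), "Sum Sq"], tolerance = 1e-10)
    expect_equal(res$table$df[1:3], ref[c("A", "B", "A:B"), "Df"])
  })
})

test_that("identical group multisets give no effect and large p", {
  v <- c(1.2, 3.4, 5.6, 7.8)
  dat <- data.frame(y = c(v, v), g = rep(c("a", "b"), each = 4))
  res <- permanova(y ~ g, dat, n_perm = 499, seed = 13)
  expect_lt(abs(res$table$r2[1]), 1e-12)
  expect_gt(res$table$p[1], 0.5)
})

test_that("r2 values sum to one and df sum to n-1", {
  withr::with_seed(14, {
    dat <- data.frame(y1 = rnorm(20), y2 = rnorm(20),
                      age = factor(rep(c("s", "v"), 10)),
                      loc = factor(rep(c("A", "B"), each = 10)))
    res <- permanova(cbind(y1, y2) ~ age * loc, dat, n_perm = 0)
    tab <- res$table
    expect_equal(sum(tab$r2[tab$term != "Total"]), 1, tolerance = 1e-12)
    expect_equal(sum(tab$df[tab$term != "Total"]), 19)
  })
})

test_that("pseudo-F and r2 match vegan's adonis2 on multivariate data", {
  withr::with_seed(15, {
    y <- matrix(rnorm(60), 20, 3)
    dat <- data.frame(g = factor(rep(c("a", "b"), 10)),
                      h = factor(rep(c("u", "v"), each = 10)))
    res <- permanova(y ~ g * h, cbind(data.frame(y = I(y)), dat), n_perm = 0)
    ref <- vegan::adonis2(y ~ g * h, data = dat, method = "euclidean",
                          permutations = 2, by = "terms")
    expect_equal(res$table$ss[1:3], ref$SumOfSqs[1:3], tolerance = 1e-8)
    expect_equal(res$table$pseudo_F[1:3], ref$F[1:3], tolerance = 1e-8)
  })
})

test_that("degenerate constant response is an error", {
  dat <- data.frame(y = rep(1, 8), g = factor(rep(c("a", "b"), 4)))
  expect_error(permanova(y ~ g, dat, n_perm = 0), "degenerate")
})

# --- DAPC -------------------------------------------------------------------

test_that("default retains one third of the individuals as PCs", {
  withr::with_seed(21, {
    x <- matrix(rnorm(105 * 50), 105, 50)
    g <- factor(rep(c("A", "B", "C"), each = 35))
    res <- dapc(x, g)
    expect_equal(res$n_pcs, 35L)
    expect_equal(dim(res$posterior), c(105L, 3L))
    expect_equal(unname(rowSums(res$posterior)), rep(1, 105), tolerance = 1e-9)
  })
})

test_that("disjoint fixed alleles give perfect reassignment", {
  withr::with_seed(22, {
    x <- rbind(matrix(0, 15, 10), matrix(2, 15, 10))
    x <- x + matrix(rnorm(300, sd = 0.01), 30, 10)
    g <- factor(rep(c("A", "B"), each = 15))
    res <- dapc(x, g, n_pcs = 5)
    expect_equal(mean(res$assignment == g), 1.0)
  })
})

test_that("with all PCs the first axis matches Fisher's discriminant direction", {
  withr::with_seed(23, {
    n <- 40
    x <- matrix(rnorm(n * 6), n, 6)
    g <- factor(rep(c("A", "B"), each = n / 2))
    x[g == "B", 1:2] <- x[g == "B", 1:2] + 1.5
    res <- dapc(x, g, n_pcs = 6)
    # independent Fisher direction on the same retained scores
    xs <- scale(x)
    pc <- prcomp(xs, center = FALSE)$x[, 1:6]
    m1 <- colMeans(pc[g == "A", ]); m2 <- colMeans(pc[g == "B", ])
    W <- (crossprod(scale(pc[g == "A", ], scale = FALSE)) +
            crossprod(scale(pc[g == "B", ], scale = FALSE)))
    d <- solve(W, m1 - m2)
    v <- res$discriminant_axes[, 1]
    cos_angle <- abs(sum(d * v)) / sqrt(sum(d^2) * sum(v^2))
    expect_gt(cos_angle, 0.999)
  })
})

test_that("DAPC scores are invariant to individual ordering", {
  withr::with_seed(24, {
    x <- matrix(rnorm(30 * 12), 30, 12)
    rownames(x) <- sprintf("i%02d", 1:30)
    g <- factor(rep(c("A", "B", "C"), 10))
    res1 <- dapc(x, g, n_pcs = 8)
    ord <- sample(30)
    res2 <- dapc(x[ord, ], g[ord], n_pcs = 8)
    s1 <- res1$scores[ord, ]
    s2 <- res2$scores
    for (k in seq_len(ncol(s1))) {
      expect_lt(min(max(abs(s1[, k] - s2[, k])),
                    max(abs(s1[, k] + s2[, k]))), 1e-8)
    }
  })
})

test_that("invalid PC counts are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  g <- factor(rep(c("A", "B"), 5))
  expect_error(dapc(x, g, n_pcs = 10), "smaller")
  expect_error(dapc(x, g, n_pcs = 0), "at least 1")
})
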