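test_that("backgrounds intersect with expressed genes except for orthologues", {
  col <- gene_set_collection(
    sets = list(s = list(genes = "g1", background_category = "protein_coding")),
    backgrounds = list(protein_coding = paste0("g", 1:10),
                       orthologue_1to1 = paste0("o", 1:700)))
  expect_setequal(build_background("protein_coding", col,
                                   c(paste0("g", 1:5), "g99")),
                  paste0("g", 1:5))
  # genome-wide orthologue background is never intersected
  expect_length(build_background("orthologue_1to1", col, "g1"), 700)
  expect_error(build_background("nope", col, "g1"), "unknown")
  expect_error(build_background("protein_coding", col, "zzz"), "empty")
})

test_that("Fisher enrichment reproduces hand-computed counts and statistics", {
  bg <- paste0("g", 1:100)
  set_genes <- paste0("g", 1:20)               # a + b = 20
  de_genes <- paste0("g", c(1:5, 21:25))       # a = 5, c = 5
  r <- fisher_enrichment(set_genes, de_genes, bg)
  expect_equal(unlist(r[c("a", "b", "c", "d")], use.names = FALSE),
               c(5, 15, 5, 75))
  expect_equal(r$odds_ratio, 5)
  expect_equal(r$fold_of_expected, (5 / 20) / (10 / 100))
  expect_equal(r$p, fisher.test(matrix(c(5, 15, 5, 75), 2))$p.value,
               tolerance = 1e-12)

  # zero overlap: odds ratio and fold are 0, p still exact
  r0 <- fisher_enrichment(paste0("g", 1:10), paste0("g", 90:99), bg)
  expect_equal(r0$odds_ratio, 0)
  expect_equal(r0$fold_of_expected, 0)
  expect_error(fisher_enrichment(paste0("x", 1:3), de_genes, bg), "disjoint")
})

test_that("Fisher p matches the enumeration oracle on random small tables", {
  set.seed(10)
  for (i in 1:200) {
    cnt <- as.vector(stats::rmultinom(1, sample(4:40, 1), runif(4, 0.05, 1)))
    if (cnt[1] + cnt[2] == 0) cnt[2] <- 1
    n <- sum(cnt)
    p_pkg <- fisher_enrichment(
      paste0("g", seq_len(cnt[1] + cnt[2])),
      paste0("g", c(seq_len(cnt[1]),
                    cnt[1] + cnt[2] + seq_len(cnt[3]))),
      paste0("g", seq_len(n)))$p
    expect_equal(p_pkg, oracle_fisher_p(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-10)
  }
})

test_that("Bonferroni adjustments multiply and cap at 1", {
  res <- data.frame(set = c("a", "b", "c"), p = c(0.01, 1e-12, 0.5))
  adj <- adjust_fisher(res, n_tests = 62)
  expect_equal(adj$p_adj, c(0.62, 6.2e-11, 1))
  sh <- data.frame(set = c("a", "b"), p = c(0.001, 0.05))
  expect_equal(adjust_binomial(sh, n_sets = 31)$p_adj, c(0.031, 1))
  expect_equal(adjust_binomial(sh, n_sets = 1)$p_adj, sh$p)
})

test_that("binomial shift reproduces the enumerated two-sided tail", {
  # background of 40 genes, half male-higher; set = 10 genes with 9 male-higher
  bg <- paste0("g", 1:40)
  de <- data.frame(gene = bg,
                   log2FD = rep(c(0.5, -0.5), each = 20))
  set_genes <- paste0("g", c(1:9, 40))   # 9 positive, 1 negative
  r <- binomial_shift(set_genes, de, bg)
  expect_equal(r$n_set, 10); expect_equal(r$k_male, 9)
  expect_equal(r$p_bg, 0.5)
  expect_equal(r$p, 22 / 1024, tolerance = 1e-12)
  expect_equal(r$shift, 0.9 - 0.5)
  expect_equal(r$p, binom.test(9, 10, 0.5)$p.value, tolerance = 1e-12)

  # set proportion equal to background: zero shift, p in the null centre
  set0 <- paste0("g", c(1:5, 21:25))
  r0 <- binomial_shift(set0, de, bg)
  expect_equal(r0$shift, 0)
  expect_gte(r0$p, 0.5)

  # Clopper-Pearson interval matches the exact binomial test
  ci <- binom.test(9, 10, 0.5)$conf.int
  expect_equal(c(r$ci_lo, r$ci_hi), as.numeric(ci), tolerance = 1e-10)

  expect_error(binomial_shift(paste0("x", 1:3), de, bg), "no informative")
})

test_that("binomial p matches enumeration on random cases", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    pr <- runif(1, 0.05, 0.95)
    probs <- dbinom(0:n, n, pr)
    p_oracle <- min(1, sum(probs[probs <= probs[k + 1] * (1 + 1e-7)]))
    expect_equal(binom.test(k, n, pr)$p.value, p_oracle, tolerance = 1e-9)
  }
})

test_that("a set equal to its background is null under both tests", {
  bg <- paste0("g", 1:50)
  de_tb <- data.frame(gene = bg, log2FD = rnorm(50))
  r <- binomial_shift(bg, de_tb, bg)
  expect_equal(r$shift, 0)
  expect_gte(r$p, 0.5)
  f <- fisher_enrichment(bg, paste0("g", 1:10), bg)
  expect_equal(f$p, 1)
  expect_equal(f$fold_of_expected, 1)
})

test_that("the suite emits sets x directions x tiers rows with flags", {
  set.seed(3)
  genes <- paste0("g", 1:600)
  sets <- lapply(stats::setNames(1:31, paste0("set", 1:31)), function(i)
    list(genes = sample(genes, 20), background_category = "protein_coding"))
  col <- gene_set_collection(sets, backgrounds = list(protein_coding = genes))
  de_tb <- data.frame(gene = genes, log2FD = rnorm(600),
                      p = runif(600))
  de_tb <- call_sex_de(de_tb)
  rep <- run_enrichment_suite(de_tb, col)
  expect_equal(nrow(rep$fisher), 31 * 2 * 3)
  expect_equal(nrow(rep$shift), 31)
  expect_true(all(rep$fisher$p_adj >= rep$fisher$p))
  expect_true(all(rep$shift$p_adj >= rep$shift$p))
  # flags monotone in raw p within a tier/direction
  for (tier in unique(rep$fisher$tier)) {
    sub <- rep$fisher[rep$fisher$tier == tier, ]
    if (any(sub$significant))
      expect_lt(max(sub$p[sub$significant]), min(sub$p[!sub$significant]))
  }
  # report round-trips to TSV
  f <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_report(rep, f)
  long <- read.delim(f)
  expect_equal(nrow(long), 31 * 7)
  expect_setequal(unique(long$test), c("fisher", "binomial_shift"))
})

test_that("planted male-biased sets are detected by both tests", {
  co <- planted_cohort(seed = 61, n_genes = 2000, set_size = 200,
                       log2fd = 0.3, n_subjects = 10)
  res <- run_sex_de(co$expression, co$samples)
  rep <- run_enrichment_suite(res$table, co$sets)
  f <- rep$fisher[rep$fisher$set == "planted" &
                    rep$fisher$direction == "male-DE" &
                    rep$fisher$tier == 0.05, ]
  expect_gt(f$odds_ratio, 1)
  expect_true(f$significant)
  s <- rep$shift[rep$shift$set == "planted", ]
  expect_gt(s$shift, 0)
  expect_true(s$significant)
  # the matched control set stays quiet
  expect_false(rep$shift$significant[rep$shift$set == "ctrl_planted"])
})

test_that("relabelling the sexes mirrors every directional statistic", {
  co <- planted_cohort(seed = 71, n_genes = 600, set_size = 60,
                       log2fd = 0.4, n_subjects = 5)
  flip <- co$samples
  flip$sex <- ifelse(co$samples$sex == "male", "female", "male")
  res_a <- run_sex_de(co$expression, co$samples)
  res_b <- run_sex_de(co$expression, flip)
  expect_equal(res_b$table$log2FD, -res_a$table$log2FD, tolerance = 1e-8)

  rep_a <- run_enrichment_suite(res_a$table, co$sets)
  rep_b <- run_enrichment_suite(res_b$table, co$sets)
  key <- function(df) df[order(df$set, df$tier, df$direction), ]
  swap <- rep_b$fisher
  swap$direction <- ifelse(swap$direction == "male-DE", "female-DE", "male-DE")
  expect_equal(key(swap)[, c("a", "b", "c", "d", "p")],
               key(rep_a$fisher)[, c("a", "b", "c", "d", "p")],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rep_b$shift$shift, -rep_a$shift$shift, tolerance = 1e-12)
  expect_equal(rep_b$shift$p, rep_a$shift$p, tolerance = 1e-9)
})
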