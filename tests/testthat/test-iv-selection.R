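test_that("genome-wide filter applies a strict inequality", {
  p <- make_panel(n = 3, pval = c(1e-9, 5e-8, 1e-7))
  kept <- filter_genomewide(p, 5e-8)
  expect_identical(kept$snp_id, "rs001")
  expect_equal(nrow(filter_genomewide(p, 1.0)), 3)
  empty <- filter_genomewide(p, 1e-300)
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "summary_panel")
})

test_that("clumping keeps the smaller-p SNP of a linked nearby pair", {
  p <- make_panel(n = 2, pos = c(1e6, 1e6 + 5e3), pval = c(1e-10, 1e-9))
  ld <- ld_info(data.frame(snp_id = p$snp_id, chrom = p$chrom, pos = p$pos),
                data.frame(snp_a = "rs001", snp_b = "rs002", r2 = 0.9))
  kept <- clump_greedy(p, ld, r2_max = 0.001, window_kb = 10000)
  expect_identical(kept$snp_id, "rs001")
})

test_that("the clumping window never spans chromosomes", {
  p <- make_panel(n = 2, chrom = c("1", "2"), pos = c(1e6, 1e6),
                  pval = c(1e-10, 1e-9))
  ld <- ld_info(data.frame(snp_id = p$snp_id, chrom = p$chrom, pos = p$pos),
                data.frame(snp_a = "rs001", snp_b = "rs002", r2 = 0.99))
  expect_equal(nrow(clump_greedy(p, ld)), 2)
})

test_that("greedy clumping matches an independent hand-trace on a 6-SNP fixture", {
  # chrom 1: A(p=1e-12, pos 1.0e6), B(1e-10, 1.4e6, r2(A,B)=0.5),
  #          C(1e-9, 1.2e6, r2(A,C)=0.0004), D(1e-8, 30e6, r2(A,D)=0.8 but far)
  # chrom 2: E(1e-11, 1e6), F(1e-7, 2e6, r2(E,F)=0.3)
  p <- make_panel(
    n = 6, snp_id = LETTERS[1:6],
    chrom = c("1", "1", "1", "1", "2", "2"),
    pos = c(1.0e6, 1.4e6, 1.2e6, 30e6, 1e6, 2e6),
    pval = c(1e-12, 1e-10, 1e-9, 1e-8, 1e-11, 1e-7)
  )
  ld <- ld_info(
    data.frame(snp_id = p$snp_id, chrom = p$chrom, pos = p$pos),
    data.frame(snp_a = c("A", "A", "A", "E"),
               snp_b = c("B", "C", "D", "F"),
               r2 = c(0.5, 0.0004, 0.8, 0.3))
  )

  # independent oracle: a literal re-trace of the rule with a data.frame queue
  greedy_trace <- function(panel, ldinfo, r2_max, window_kb) {
    df <- data.frame(id = panel$snp_id, p = panel$pval,
                     chrom = panel$chrom, pos = panel$pos,
                     stringsAsFactors = FALSE)
    pairs <- data.frame(a = c("A", "A", "A", "E"), b = c("B", "C", "D", "F"),
                        r2 = c(0.5, 0.0004, 0.8, 0.3))
    r2_of <- function(x, y) {
      hit <- (pairs$a == x & pairs$b == y) | (pairs$a == y & pairs$b == x)
      if (any(hit)) pairs$r2[hit][1] else 0
    }
    kept <- character(0)
    while (nrow(df)) {
      df <- df[order(df$p, df$pos, df$id), ]
      index <- df[1, ]
      kept <- c(kept, index$id)
      df <- df[-1, , drop = FALSE]
      if (nrow(df)) {
        rm_idx <- sapply(seq_len(nrow(df)), function(i) {
          df$chrom[i] == index$chrom &&
            abs(df$pos[i] - index$pos) <= window_kb * 1000 &&
            r2_of(index$id, df$id[i]) >= r2_max
        })
        df <- df[!rm_idx, , drop = FALSE]
      }
    }
    sort(kept)
  }

  expected <- greedy_trace(p, ld, 0.001, 10000)
  got <- sort(clump_greedy(p, ld, 0.001, 10000)$snp_id)
  expect_identical(got, expected)
  # hand expectation: A removes B (r2 0.5, 0.4 Mb); C survives (r2 < 0.001);
  # D survives (28.6 Mb away > 10 Mb); E removes F (r2 0.3, 1 Mb)
  expect_identical(got, sort(c("A", "C", "D", "E")))
})

test_that("clumping is invariant to input order and errors on missing positions", {
  p <- make_panel(n = 5, pos = seq(1e6, by = 3e6, length.out = 5),
                  pval = c(1e-12, 1e-11, 1e-10, 1e-9, 1e-8))
  ld <- ld_info(
    data.frame(snp_id = p$snp_id, chrom = p$chrom, pos = p$pos),
    data.frame(snp_a = c("rs001", "rs002"), snp_b = c("rs002", "rs003"),
               r2 = c(0.9, 0.5))
  )
  ref <- clump_greedy(p, ld)$snp_id
  for (perm in list(5:1, c(3, 1, 5, 2, 4))) {
    shuffled <- summary_panel(as.data.frame(p)[perm, ], "exposure", "continuous")
    expect_setequal(clump_greedy(shuffled, ld)$snp_id, ref)
  }
  lost <- ld_info(data.frame(snp_id = p$snp_id[-3], chrom = p$chrom[-3],
                             pos = p$pos[-3]))
  err <- tryCatch(clump_greedy(p, lost), error = identity)
  expect_s3_class(err, "mrmediate_config_error")
  expect_match(conditionMessage(err), "rs003")
})

test_that("confounder exclusion removes only strongly associated SNPs and reports them", {
  p <- make_panel(n = 3)
  cat1 <- confounder_catalog(data.frame(
    snp_id = c("rs001", "rs002"), trait = c("smoking", "bmi"),
    pval = c(1e-9, 1e-6)
  ))
  res <- exclude_confounder_snps(p, cat1, 5e-8)
  expect_setequal(res$panel$snp_id, c("rs002", "rs003"))
  expect_equal(res$report$snp_id, "rs001")
  expect_equal(res$report$trait, "smoking")
  # empty catalog leaves the panel unchanged
  res0 <- exclude_confounder_snps(p, confounder_catalog(), 5e-8)
  expect_equal(nrow(res0$panel), 3)
  expect_equal(nrow(res0$report), 0)
})

test_that("the F statistic is the squared z-score", {
  expect_equal(per_snp_f(0.02, 0.002), 100)
  expect_equal(per_snp_f(0, 1), 0)
  expect_equal(per_snp_f(0.01, 0.005), 4)
  p <- make_panel(n = 2, beta = c(0.02, 0.01), se = c(0.002, 0.005))
  expect_equal(per_snp_f(p), c(100, 4))
})

test_that("select_instruments composes the four screens with an audit trail", {
  # five SNPs engineered so each stage removes exactly one:
  # rs005 fails significance; rs002 clumped into rs001; rs003 confounder-linked;
  # rs004 weak (F = 4); rs001 survives
  p <- make_panel(
    n = 5,
    pos = c(1e6, 1.5e6, 40e6, 80e6, 120e6),
    beta = c(0.05, 0.05, 0.05, 0.01, 0.05),
    se = c(0.005, 0.005, 0.005, 0.005, 0.005),
    pval = c(1e-12, 1e-10, 1e-11, 1e-9, 1e-7)
  )
  ld <- ld_info(data.frame(snp_id = p$snp_id, chrom = p$chrom, pos = p$pos),
                data.frame(snp_a = "rs001", snp_b = "rs002", r2 = 0.8))
  cat1 <- confounder_catalog(data.frame(snp_id = "rs003", trait = "bmi",
                                        pval = 1e-10))
  res <- select_instruments(p, ld, cat1, iv_config())
  expect_identical(unname(res$audit), c(5L, 4L, 3L, 2L, 1L))
  expect_identical(res$panel$snp_id, "rs001")
  # every survivor satisfies all four predicates simultaneously
  expect_true(all(res$panel$pval < 5e-8))
  expect_true(all(per_snp_f(res$panel) > 10))
  expect_false(any(res$panel$snp_id %in% res$exclusions$snp_id))
})

test_that("select_instruments errors when nothing survives", {
  p <- make_panel(n = 3)
  ld <- ld_info(data.frame(snp_id = p$snp_id, chrom = p$chrom, pos = p$pos))
  expect_mrm_error(
    select_instruments(p, ld, confounder_catalog(), iv_config(p_threshold = 0)),
    "mrmediate_empty_instruments"
  )
})

test_that("each selection stage yields a subset of its input", {
  tr <- simulation_truth(n_snp = 30, theta_direct = 0.2, seed = 11)
  sim <- simulate_panels(tr, confounder_snp_ids = c("rs00003", "rs00017"))
  res <- select_instruments(sim$exposure, sim$ld, sim$catalog)
  expect_true(all(diff(unname(res$audit)) <= 0))
  expect_true(all(res$panel$snp_id %in% sim$exposure$snp_id))
  expect_false(any(c("rs00003", "rs00017") %in% res$panel$snp_id))
})
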