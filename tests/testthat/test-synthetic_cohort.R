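# The family-cohort generator: configuration contracts, transmission
# algebra, index standardisation, the rGE channel and outcome calibration.

test_that("configuration invariants are enforced with informative errors", {
  expect_error(cohort_config(zygosity_mix = c(mz = 0.6, dz = 0.6)),
               class = "gxefam_config_error")
  expect_error(cohort_config(maf_low = 0), class = "gxefam_config_error")
  expect_error(cohort_config(maf_low = 0.4, maf_high = 0.2),
               class = "gxefam_config_error")
  expect_error(cohort_config(maf_high = 0.7), class = "gxefam_config_error")
  expect_error(cohort_config(ses_base_rate = 1), class = "gxefam_config_error")
  expect_error(cohort_config(missing_genotype_rate = 1),
               class = "gxefam_config_error")
  expect_error(
    cohort_config(effects = default_effects(cito = list(beta_cog = Inf))),
    class = "gxefam_config_error")
  expect_error(
    cohort_config(effects = default_effects(math7 = list(family_sd = -1))),
    class = "gxefam_config_error")
  # degenerate-but-legal boundary: a single shared allele frequency
  expect_s3_class(cohort_config(maf_low = 0.3, maf_high = 0.3),
                  "cohort_config")
})

test_that("parent genotypes have binomial(2, p) moments", {
  cfg <- cohort_config(n_families = 1000, n_loci = 400,
                       maf_low = 0.5, maf_high = 0.5,
                       missing_genotype_rate = 0, seed = 21)
  par <- simulate_parents(cfg)
  g <- par$geno
  n <- length(g)
  # dosage ~ binomial(2, 1/2): mean 1, variance 1/2
  mc_se_mean <- sqrt(0.5 / n)
  expect_lt(abs(mean(g) - 1), 3 * mc_se_mean)
  expect_lt(abs(stats::var(as.vector(g)) - 0.5), 0.01)
})

test_that("an empty cohort still carries the full column schema", {
  cfg <- cohort_config(n_families = 0, n_loci = 10)
  par <- simulate_parents(cfg)
  expect_identical(nrow(par$individuals), 0L)
  expect_true(all(c("person_id", "family_id", "role", "zygosity", "pgi_cog",
                    "ses", "math7", "cito_z", "track", "attain")
                  %in% names(par$individuals)))
})

test_that("meiosis is Mendelian, duplicates MZ pairs and respects forced transmission", {
  cfg <- cohort_config(n_families = 300, n_loci = 80,
                       missing_genotype_rate = 0, seed = 31)
  co <- meiose_children(simulate_parents(cfg), cfg)
  expect_true(check_mendelian(co))
  ind <- co$individuals
  mz <- ind[ind$zygosity == "MZ" & ind$role %in% c("twin1", "twin2"), ]
  fams <- unique(mz$family_id)
  expect_gt(length(fams), 0)
  for (f in fams) {
    expect_identical(co$geno[paste0(f, "_twin1"), ],
                     co$geno[paste0(f, "_twin2"), ])
  }
  # forced transmission: homozygous parents pin the child allele
  is_child <- ind$role %in% child_roles
  gc <- co$geno[ind$person_id[is_child], ]
  gf <- co$geno[paste0(ind$family_id[is_child], "_father"), ]
  gm <- co$geno[paste0(ind$family_id[is_child], "_mother"), ]
  both0 <- gf == 0 & gm == 0
  both2 <- gf == 2 & gm == 2
  expect_true(all(gc[both0] == 0))
  expect_true(all(gc[both2] == 2))
  # a family without parents is a structural error
  broken <- co
  keep <- broken$individuals$person_id != paste0(fams[1], "_father")
  broken$individuals <- broken$individuals[keep, ]
  expect_error(meiose_children(broken, cfg), class = "gxefam_structure_error")
})

test_that("kinship correlations of the indices match transmission algebra", {
  # dizygotic co-twins share half the segregating variation; a child and the
  # mid-parent average correlate at sqrt(1/2)
  cfg <- cohort_config(n_families = 2500, n_loci = 300,
                       zygosity_mix = c(mz = 0, dz = 1, mz_sib = 0, dz_sib = 0),
                       missing_genotype_rate = 0, seed = 41)
  co <- compute_pgis(meiose_children(simulate_parents(cfg), cfg), cfg)
  ind <- co$individuals
  t1 <- ind$pgi_cog[match(paste0(unique(ind$family_id), "_twin1"), ind$person_id)]
  t2 <- ind$pgi_cog[match(paste0(unique(ind$family_id), "_twin2"), ind$person_id)]
  fa <- ind$pgi_cog[match(paste0(unique(ind$family_id), "_father"), ind$person_id)]
  mo <- ind$pgi_cog[match(paste0(unique(ind$family_id), "_mother"), ind$person_id)]
  n <- length(t1)
  se_r <- function(r) (1 - r^2) / sqrt(n)
  expect_lt(abs(cor(t1, t2) - 0.5), 3 * se_r(0.5))
  expect_lt(abs(cor(t1, (fa + mo) / 2) - sqrt(0.5)), 3 * se_r(sqrt(0.5)))
  expect_lt(abs(cor(t1, fa) - 0.5), 3 * se_r(0.5))
})

test_that("index standardisation hits the genotyped-children reference exactly", {
  cfg <- small_config(missing_genotype_rate = 0.3)
  co <- simulate_cohort(cfg)
  ind <- co$individuals
  ref <- ind$role %in% child_roles & !ind$geno_missing
  expect_lt(abs(mean(ind$pgi_cog[ref])), 1e-8)
  expect_lt(abs(stats::var(ind$pgi_cog[ref]) - 1), 1e-8)
  expect_lt(abs(stats::var(ind$pgi_noncog[ref]) - 1), 1e-8)
  # masked persons have missing observed indices but retained ground truth
  expect_true(all(is.na(ind$pgi_cog[ind$geno_missing])))
  expect_true(all(!is.na(ind$pgi_cog_true)))
  # monozygotic co-twins have identical indices
  mzf <- unique(ind$family_id[ind$zygosity == "MZ"])
  i1 <- match(paste0(mzf, "_twin1"), ind$person_id)
  i2 <- match(paste0(mzf, "_twin2"), ind$person_id)
  expect_equal(ind$pgi_cog_true[i1], ind$pgi_cog_true[i2])
})

test_that("degenerate index weights are rejected", {
  cfg <- small_config()
  co <- meiose_children(simulate_parents(cfg), cfg)
  co$pgi_weights <- matrix(0, cfg$n_loci, 2,
                           dimnames = list(NULL, c("cog", "noncog")))
  expect_error(compute_pgis(co, cfg), class = "gxefam_degenerate_error")
})

test_that("the rGE dial works and parental indices capture the channel", {
  base <- function(r, seed = 51) {
    cfg <- cohort_config(n_families = 1500, n_loci = 150, rge_strength = r,
                         missing_genotype_rate = 0, seed = seed)
    co <- assign_ses(compute_pgis(meiose_children(simulate_parents(cfg), cfg),
                                  cfg), cfg)
    co$individuals
  }
  ind0 <- base(0)
  ch0 <- ind0[ind0$role %in% child_roles, ]
  expect_lt(abs(cor(ch0$pgi_cog, ch0$ses)), 3 / sqrt(nrow(ch0)))
  # monotone non-decreasing in rge_strength
  rs <- c(0, 0.3, 0.7, 1.2)
  cors <- vapply(rs, function(r) {
    ind <- base(r)
    ch <- ind[ind$role %in% child_roles, ]
    cor(ch$pgi_cog, ch$ses)
  }, 0)
  expect_true(all(diff(cors) > -0.02))
  expect_gt(cors[4], cors[1] + 0.05)
  # conditioning on both parents' indices absorbs the rGE association
  ind <- base(0.5)
  ch <- ind[ind$role %in% child_roles & !is.na(ind$pgi_cog_f), ]
  raw <- coef(summary(lm(ses ~ pgi_cog, ch)))["pgi_cog", ]
  ctl <- coef(summary(lm(ses ~ pgi_cog + pgi_cog_f + pgi_cog_m +
                           pgi_noncog_f + pgi_noncog_m, ch)))["pgi_cog", ]
  expect_gt(raw["Estimate"], 3 * raw["Std. Error"])
  expect_lt(abs(ctl["Estimate"]), 3 * ctl["Std. Error"])
})

test_that("the high-SES share tracks the configured base rate", {
  cfg <- cohort_config(n_families = 2000, n_loci = 100,
                       ses_base_rate = 0.41, seed = 61)
  co <- simulate_cohort(cfg)
  fam_ses <- tapply(co$individuals$ses, co$individuals$family_id, max)
  expect_lt(abs(mean(fam_ses) - 0.41),
            3 * sqrt(0.41 * 0.59 / length(fam_ses)) + 0.01)
})

test_that("outcome scales match their calibration", {
  cfg <- cohort_config(n_families = 1500, n_loci = 100, seed = 71)
  co <- simulate_cohort(cfg)
  ch <- co$individuals[co$individuals$role %in% child_roles, ]
  expect_true(all(ch$math7 %in% 1:5) && all(ch$read10 %in% 1:5))
  expect_true(all(ch$cito_raw >= 501 & ch$cito_raw <= 550))
  expect_true(all(ch$track %in% 0:1) && all(ch$attain %in% 0:1))
  expect_lt(abs(mean(ch$cito_raw) - 538.9), 0.7)
  expect_lt(abs(sd(ch$cito_raw) - 9), 0.5)
  expect_lt(abs(sd(ch$math7) - 0.9), 0.08)
  expect_lt(abs(mean(ch$track) - 0.50), 0.04)
  expect_lt(abs(mean(ch$attain) - 0.35), 0.04)
})

test_that("a null structural model yields flat stratified slopes", {
  null_eff <- default_effects()
  for (o in names(null_eff))
    null_eff[[o]][c("beta_cog", "beta_noncog", "beta_ses",
                    "gamma_cog", "gamma_noncog")] <- list(0, 0, 0, 0, 0)
  for (o in names(null_eff)) null_eff[[o]]$family_sd <- 0
  cfg <- cohort_config(n_families = 1200, n_loci = 100, effects = null_eff,
                       seed = 81)
  co <- simulate_cohort(cfg)
  ch <- co$individuals[co$individuals$role %in% child_roles &
                         !is.na(co$individuals$pgi_cog), ]
  for (s in 0:1) {
    sl <- coef(summary(lm(cito_z ~ pgi_cog, ch[ch$ses == s, ])))["pgi_cog", ]
    expect_lt(abs(sl["Estimate"]), 3 * sl["Std. Error"])
  }
})

test_that("identical configurations reproduce bit-identical cohorts", {
  cfg <- small_config()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$geno, b$geno)
  c2 <- simulate_cohort(small_config(), seed = 12)
  expect_false(identical(a$individuals, c2$individuals))
})

test_that("a cohort round-trips through the delimited table and sidecar", {
  cfg <- cohort_config(n_families = 40, n_loci = 25, seed = 91)
  co <- simulate_cohort(cfg)
  stem <- file.path(tempdir(), "cohort-roundtrip")
  write_cohort(co, stem)
  back <- read_cohort(stem)
  expect_equal(back$individuals$person_id, co$individuals$person_id)
  expect_equal(back$individuals$pgi_cog, co$individuals$pgi_cog,
               tolerance = 1e-12)
  expect_equal(back$individuals$math7, co$individuals$math7)
  # observed genotypes: masked persons read back as missing
  miss <- co$individuals$geno_missing
  expect_true(all(is.na(back$geno[miss, ])))
  expect_equal(back$geno[!miss, ], co$geno[co$individuals$person_id[!miss], ])
  expect_equal(back$config$seed, cfg$seed)
  expect_equal(unname(back$config$zygosity_mix), unname(cfg$zygosity_mix))
  # the read-back cohort feeds the analysis stages unchanged
  s1 <- build_between(co, "math7", seed = 3)
  s2 <- build_between(back, "math7", seed = 3)
  expect_identical(s1$data$person_id, s2$data$person_id)
})
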