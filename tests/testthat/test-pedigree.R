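test_that("pedigree construction validates structure", {
  # 4-line nuclear family: 1 family, 2 founders
  tf <- tempfile(fileext = ".fam")
  writeLines(c("1 f 0 0 1", "1 m 0 0 2", "1 a f m 1", "1 b f m 2"), tf)
  ped <- read_pedigree(tf)
  s <- summary(ped)
  expect_equal(s$n_families, 1L)
  expect_equal(sum(s$founders_per_family), 2L)
  expect_equal(s$n, 4L)

  # child listed as its own grandparent -> cycle
  expect_error(
    pedigree(1, c("a", "b", "c"), c("b", "c", 0), c("x", "x", 0),
             c(1, 1, 2)),
    "unresolved|cycle")
  expect_error(
    pedigree(1, c("a", "b", "c", "x"), c("b", "c", "a", 0),
             c("x", "x", "x", 0), c(1, 1, 1, 2)),
    "cycle")

  expect_error(pedigree(1, c("a", "a"), c(0, 0), c(0, 0), c(1, 2)),
               "duplicated")
  expect_error(pedigree(1, c("a", "b"), c(0, "z"), c(0, "a"), c(2, 1)),
               "unresolved parent")
  expect_error(pedigree(1, c("a", "b"), c(0, "a"), c(0, 0), c(1, 1)),
               "half-specified")
})

test_that("synthetic pedigrees round-trip through .fam write+load", {
  cfg <- sim_config(n_families = 104, seed = 5)
  ped <- simulate_pedigrees(cfg)
  tf <- tempfile(fileext = ".fam")
  write_pedigree(ped, tf)
  ped2 <- read_pedigree(tf)
  expect_equal(as.data.frame(ped2)[c("fid", "id", "father", "mother", "sex")],
               as.data.frame(ped)[c("fid", "id", "father", "mother", "sex")])
})

test_that("kinship matches textbook coefficients", {
  k <- kinship_matrix(ped_nuclear(2))$phi
  expect_equal(unname(k["1:f", "1:k1"]), 0.25)    # parent-offspring
  expect_equal(unname(k["1:k1", "1:k2"]), 0.25)   # full siblings
  expect_equal(unname(k["1:f", "1:m"]), 0)        # spouses unrelated

  kh <- kinship_matrix(ped_half_and_cousins())$phi
  expect_equal(unname(kh["1:h1", "1:h2"]), 0.125)  # half-siblings
  expect_equal(unname(kh["1:x1", "1:x2"]), 0.0625) # first cousins

  # offspring of a full-sib mating: phi_self = (1 + 1/4)/2
  ki <- kinship_matrix(ped_inbred())$phi
  expect_equal(unname(ki["1:x", "1:x"]), 0.625)
})

test_that("2*Phi is positive semi-definite on generated pedigrees", {
  for (seed in 1:3) {
    ped <- simulate_pedigrees(sim_config(n_families = 25, seed = seed))
    phi <- kinship_matrix(ped)$phi
    ev <- eigen(2 * phi, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("kinship agrees with Monte-Carlo gene-drop IBD probabilities", {
  ped <- ped_half_and_cousins()   # 11 members incl. half-sibs and cousins
  ped <- ped[ped$id %in% c("f1", "f2", "m", "h1", "h2", "s1", "w1", "x1"), ]
  ped <- pedigree(ped$fid, ped$id, ped$father, ped$mother, ped$sex)
  phi <- kinship_matrix(ped)$phi
  mc <- oracle_kinship_mc(ped, ndrops = 1e5)
  tol <- 3 * pmax(mc$se, 1e-4)
  expect_true(all(abs(mc$phi - phi[rownames(mc$phi), colnames(mc$phi)])
                  <= tol))
})

test_that("pair classification follows path structure, not kinship alone", {
  ped <- ped_three_gen()
  # parent-offspring and full sibs share phi = 1/4 but separate labels
  expect_equal(classify_pair(ped, "gf", "c1")$description, "parent-offspring")
  expect_equal(classify_pair(ped, "c1", "c2")$description, "siblings")
  expect_equal(classify_pair(ped, "gf", "c1")$degree, 1)
  # grandparent vs avuncular both 2nd degree, distinguished by paths
  gp <- classify_pair(ped, "gf", "g1")
  av <- classify_pair(ped, "c2", "g1")
  expect_equal(gp$description, "grandparent-grandchild")
  expect_equal(av$description, "avuncular")
  expect_equal(gp$degree, 2)
  expect_equal(av$degree, 2)
  # in-marrying spouse is unrelated to the grandparents
  expect_equal(classify_pair(ped, "gf", "s1")$description, "unrelated")

  ph <- ped_half_and_cousins()
  expect_equal(classify_pair(ph, "h1", "h2")$description, "half-siblings")
  expect_equal(classify_pair(ph, "h1", "h2")$degree, 2)
  expect_equal(classify_pair(ph, "x1", "x2")$description, "1st cousins")
  expect_equal(classify_pair(ph, "x1", "x2")$degree, 3)
  # h2 shares only the mother with x1's parent s1
  expect_equal(classify_pair(ph, "h2", "x1")$description, "half avuncular")

  # symmetry in (i, j)
  for (pair in list(c("gf", "g1"), c("c2", "g1"), c("c1", "s1"))) {
    a <- classify_pair(ped, pair[1], pair[2])
    b <- classify_pair(ped, pair[2], pair[1])
    expect_identical(a, b)
  }
})

test_that("relationship counts enumerate every within-family pair once", {
  counts <- count_relationships(ped_nuclear(2))
  get <- function(d) counts$n_pairs[counts$description == d]
  expect_equal(get("parent-offspring"), 4L)
  expect_equal(get("siblings"), 1L)
  expect_equal(get("unrelated"), 1L)   # the spousal pair
  expect_equal(sum(counts$n_pairs), choose(4, 2))

  # grand total over labels equals sum over families of n*(n-1)/2
  ped <- simulate_pedigrees(sim_config(n_families = 20, seed = 9))
  counts <- count_relationships(ped)
  sizes <- table(ped$fid)
  expect_equal(sum(counts$n_pairs), sum(choose(sizes, 2)))
  expect_equal(attr(counts, "total_relative_pairs"),
               relationship_total(counts))
})

test_that("printed relationship table total reproduces from per-row counts", {
  tab <- read.delim(system.file("extdata", "table6_relationship_counts.tsv",
                                package = "famerv"))
  expect_true(all(tab$description %in% relationship_vocabulary()))
  expect_equal(relationship_total(tab), 3189L)
})
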