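test_that("sequence types group identical sequences, case-insensitively", {
  st <- assign_sts(c(a = "ACGT", b = "ACGT", c = "ACGA"))
  expect_equal(st$n_types, 2L)
  a <- st$assignment
  expect_equal(a$type[a$id == "a"], a$type[a$id == "b"])
  expect_false(a$type[a$id == "a"] == a$type[a$id == "c"])
  expect_equal(a$type[a$id == "a"], "ST-1") # largest group first
  st2 <- assign_sts(c(x = "acgt", y = "ACGT"))
  expect_equal(st2$n_types, 1L)
  st3 <- assign_sts(c(p = "AA", q = "CC", r = "GG"))
  expect_equal(st3$n_types, 3L)
  expect_equal(st3$n_singletons, 3L)
  expect_error(assign_sts(c(a = "")), "empty")
})

test_that("ST labels form a partition (equivalence classes)", {
  set.seed(41)
  seqs <- setNames(sample(c("AAA", "CCC", "GGG", "TTT"), 30, TRUE),
                   paste0("s", 1:30))
  st <- assign_sts(seqs)
  # same label <=> same sequence, for every pair
  lab <- setNames(st$assignment$type, st$assignment$id)
  for (i in names(seqs)) for (j in names(seqs))
    expect_equal(lab[[i]] == lab[[j]], seqs[[i]] == seqs[[j]])
})

test_that("genomic types are single-linkage components of the ANI/coverage graph", {
  # chain a-b, b-c qualifies; the weak a-c pair does not break transitivity
  tab <- data.frame(id_a = c("a", "b", "a"), id_b = c("b", "c", "c"),
                    ani = c(85, 85, 70), coverage = c(70, 70, 50))
  res <- cluster_pgts(tab)
  lab <- setNames(res$assignment$type, res$assignment$id)
  expect_equal(res$n_types, 1L)
  expect_equal(unname(lab["a"]), unname(lab["c"]))
  # the AND rule: high ANI with low coverage is not an edge
  tab2 <- data.frame(id_a = "a", id_b = "b", ani = 90, coverage = 50)
  expect_equal(cluster_pgts(tab2)$n_types, 2L)
  # thresholds are inclusive
  tab3 <- data.frame(id_a = "a", id_b = "b", ani = 80, coverage = 60)
  expect_equal(cluster_pgts(tab3)$n_types, 1L)
  # isolated genomes become singletons
  res4 <- cluster_pgts(tab2, ids = letters[1:5])
  expect_equal(res4$n_types, 5L)
  expect_equal(res4$n_singletons, 5L)
  expect_error(cluster_pgts(data.frame(id_a = "a", id_b = "b",
                                       ani = 101, coverage = 50)), "0, 100")
})

test_that("genomic type clustering is invariant to record order and pair direction", {
  set.seed(42)
  n <- 8
  pairs <- t(combn(letters[1:n], 2))
  tab <- data.frame(id_a = pairs[, 1], id_b = pairs[, 2],
                    ani = runif(nrow(pairs), 60, 100),
                    coverage = runif(nrow(pairs), 40, 100))
  ref <- cluster_pgts(tab)$assignment
  shuffled <- tab[sample(nrow(tab)), ]
  flip <- sample(c(TRUE, FALSE), nrow(shuffled), TRUE)
  tmp <- shuffled$id_a[flip]
  shuffled$id_a[flip] <- shuffled$id_b[flip]
  shuffled$id_b[flip] <- tmp
  got <- cluster_pgts(shuffled)$assignment
  expect_identical(ref[order(ref$id), ], got[order(got$id), ],
                   ignore_attr = TRUE)
})

test_that("binary Bray-Curtis matches hand values and vegan", {
  expect_equal(bray_curtis_binary(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(bray_curtis_binary(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(bray_curtis_binary(c(1, 0, 0), c(0, 1, 1)), 1)
  expect_error(bray_curtis_binary(c(0, 0), c(0, 0)), "undefined")
  expect_error(bray_curtis_binary(c(1, 0), c(1, 0, 1)), "equal length")
  set.seed(43)
  for (i in 1:20) {
    x <- rbinom(10, 1, 0.5); y <- rbinom(10, 1, 0.5)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(bray_curtis_binary(x, y),
                 as.numeric(vegan::vegdist(rbind(x, y), "bray")),
                 tolerance = 1e-12)
  }
})

test_that("phenotype groups respect the dissimilarity cut", {
  # two planted tight blocks: within-block dissimilarity < 0.1, between > 0.5
  base1 <- c(rep(1, 10), rep(0, 10))
  base2 <- c(rep(0, 10), rep(1, 10))
  flip1 <- function(v) { v[1] <- 1 - v[1]; v }
  profiles <- rbind(base1, flip1(base1), base1,
                    base2, flip1(base2), base2)
  rownames(profiles) <- paste0("s", 1:6)
  res <- phenotype_groups(profiles, "strains", cut = 0.2)
  expect_equal(res$n_types, 2L)
  lab <- setNames(res$assignment$type, res$assignment$id)
  expect_length(unique(lab[c("s1", "s2", "s3")]), 1L)
  expect_length(unique(lab[c("s4", "s5", "s6")]), 1L)
  # identical strain profiles always share a group
  expect_equal(unname(lab["s1"]), unname(lab["s3"]))
  # cut = 0 groups only identical profiles; cut = 1 collapses to one group
  expect_equal(phenotype_groups(profiles, "strains", cut = 0)$n_types, 4L)
  expect_equal(phenotype_groups(profiles, "strains", cut = 1)$n_types, 1L)
})

test_that("phenotype grouping works on the phage axis and excludes empty profiles", {
  set.seed(44)
  m <- random_binary(8, 6, 0.5)
  m[, 3] <- 0L
  colnames(m) <- paste0("p", 1:6); rownames(m) <- paste0("s", 1:8)
  expect_warning(res <- phenotype_groups(m, "phages", cut = 0.2), "all-zero")
  expect_false("p3" %in% res$assignment$id)
  expect_equal(nrow(res$assignment), 5L)
  # all profiles mutually farther apart than the cut -> all singletons
  sep <- rbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 0, 0), c(0, 0, 0, 0, 1, 1))
  rownames(sep) <- paste0("x", 1:3)
  expect_equal(phenotype_groups(sep, "strains", cut = 0.2)$n_singletons, 3L)
})

test_that("type composition tables count labels per site", {
  st <- assign_sts(c(a = "AA", b = "AA", c = "CC", d = "CC", e = "AA"))
  md <- data.frame(id = letters[1:5], entity_class = "strain",
                   site = c("T", "T", "Y", "Y", "Y"),
                   region = c("Mexico", "Mexico", "Mexico", "Mexico", "Mexico"))
  tab <- type_composition(st, md)
  expect_equal(unname(tab["T", "ST-1"]), 2L)
  expect_equal(unname(tab["Y", "ST-1"]), 1L)
  expect_equal(unname(tab["Y", "ST-2"]), 2L)
  expect_equal(sum(tab), 5L)
})
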