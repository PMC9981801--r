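test_that("lineage distance counts parent-child links", {
  ped <- cousin_pedigree()
  expect_equal(lineage_distance(ped, "gp1", "sib1"), 1)
  expect_equal(lineage_distance(ped, "sib1", "sib1"), 0)
  expect_equal(lineage_distance(ped, "gp1", "cous1"), 2)
  expect_true(is.na(lineage_distance(ped, "sib1", "sib2")))
  expect_error(lineage_distance(ped, "nobody", "sib1"), "unknown")
})

test_that("lineage distances in generated pedigrees match breadth-first enumeration", {
  ped <- generate_pedigree(3, seed = 7)
  m <- ped$members
  # oracle: explicit level-by-level parent expansion
  bfs_depth <- function(anc, desc) {
    level <- desc
    d <- 0L
    while (length(level)) {
      if (anc %in% level) return(d)
      level <- unlist(lapply(level, function(id) {
        p <- c(ped$father[[id]], ped$mother[[id]])
        p[p != "0"]
      }))
      d <- d + 1L
    }
    NA_integer_
  }
  for (desc in m$id[m$generation == 3L]) {
    for (anc in m$id) {
      expect_identical(lineage_distance(ped, anc, desc),
                       bfs_depth(anc, desc))
    }
  }
})

test_that("direct coefficients follow the halving rule", {
  ped <- cousin_pedigree()
  expect_equal(direct_coefficient(ped, "gp1", "sib1"), 0.5)  # parent-child
  expect_equal(direct_coefficient(ped, "sib1", "sib1"), 1)   # self, M = 0
  expect_equal(direct_coefficient(ped, "gp1", "cous1"), 0.25)
  # great-grandparent: extend one generation below the cousins
  df <- ped$members
  df <- rbind(df, data.frame(id = "ggc", father = "cous1", mother = "cous2",
                             affected = 0L))
  expect_error(pedigree(df), "inbred")  # cousins are related: rejected
  df$mother[df$id == "ggc"] <- "0"
  ped2 <- pedigree(df)
  expect_equal(direct_coefficient(ped2, "gp1", "ggc"), 0.125)
  expect_error(direct_coefficient(ped, "sib1", "sib2"), "direct line")
})

test_that("most-recent common ancestors exclude superseded ancestors", {
  ped <- cousin_pedigree()
  expect_setequal(mrca_pair(ped, "sib1", "sib2"), c("gp1", "gp2"))
  expect_setequal(mrca_pair(ped, "cous1", "cous2"), c("gp1", "gp2"))
  expect_identical(mrca_pair(ped, "gp1", "sp1"), character(0))
  # half-siblings share exactly the one common parent
  half <- pedigree(data.frame(
    id = c("f", "m1", "m2", "h1", "h2"),
    father = c("0", "0", "0", "f", "f"),
    mother = c("0", "0", "0", "m1", "m2"),
    affected = 0L))
  expect_identical(mrca_pair(half, "h1", "h2"), "f")
  expect_equal(genetic_coefficient(half, "h1", "h2"), 0.25)
})

test_that("genetic coefficients reproduce the classic worked values", {
  ped <- cousin_pedigree()
  expect_equal(genetic_coefficient(ped, "gp1", "sib1"), 0.5)    # parent-child
  expect_equal(genetic_coefficient(ped, "sib1", "sib2"), 0.5)   # full sibs
  expect_equal(genetic_coefficient(ped, "cous1", "cous2"), 0.125)  # cousins
  expect_equal(genetic_coefficient(ped, "sib1", "cous2"), 0.25) # avuncular
  expect_equal(genetic_coefficient(ped, "gp1", "sp1"), 0)       # unrelated
  expect_equal(genetic_coefficient(ped, "gp1", "gp1"), 1)
})

test_that("MRCA coefficients equal brute-force path enumeration on generated pedigrees", {
  for (s in c(3, 7, 21)) {
    for (g in 2:4) {
      ped <- generate_pedigree(g, affected_fraction = 0.3, seed = s)
      ids <- ped$members$id
      # all pairs on <= 3 generations, a sample of pairs on 4
      pairs <- utils::combn(ids, 2)
      if (ncol(pairs) > 150) {
        set.seed(s)
        pairs <- pairs[, sample(ncol(pairs), 150)]
      }
      for (k in seq_len(ncol(pairs))) {
        X <- pairs[1, k]
        Y <- pairs[2, k]
        expect_equal(genetic_coefficient(ped, X, Y),
                     path_sum_oracle(ped, X, Y),
                     tolerance = 1e-12,
                     label = sprintf("pair (%s,%s) seed %d gen %d",
                                     X, Y, s, g))
      }
    }
  }
})

test_that("genetic coefficients are symmetric and bounded", {
  ped <- generate_pedigree(4, affected_fraction = 0.5, seed = 5)
  ids <- ped$members$id
  set.seed(1)
  for (k in 1:40) {
    xy <- sample(ids, 2)
    kxy <- genetic_coefficient(ped, xy[1], xy[2])
    expect_equal(kxy, genetic_coefficient(ped, xy[2], xy[1]))
    expect_gte(kxy, 0)
    expect_lte(kxy, 1)
  }
  expect_true(all(diff(0.5^(0:6)) < 0))  # halving strictly decreases with M
})

test_that("familial risk sums coefficients over affected relatives", {
  none <- cousin_pedigree(affected = c())
  expect_equal(familial_risk(none, "cous1"), 0)

  one_parent <- cousin_pedigree(affected = c(sib1 = 1))
  expect_equal(familial_risk(one_parent, "cous1"), 0.5)

  ped <- generate_pedigree(4, affected_fraction = 0.4, seed = 13)
  R <- ped$members$id[nrow(ped$members)]
  affected <- setdiff(ped$members$id[ped$members$affected == 1L], R)
  loop <- 0
  for (P in affected) loop <- loop + genetic_coefficient(ped, R, P)
  expect_equal(familial_risk(ped, R), loop)
  # affected proband: own flag never contributes
  ped$members$affected[ped$members$id == R] <- 1L
  expect_equal(familial_risk(ped, R), loop)
})

test_that("pedigree I/O round-trips and rejects malformed input", {
  ped <- generate_pedigree(3, affected_fraction = 0.5, seed = 2)
  path <- tempfile(fileext = ".ped")
  write_pedigree(ped, path)
  back <- read_pedigree(path)
  expect_equal(back$members[, c("id", "father", "mother", "affected")],
               ped$members[, c("id", "father", "mother", "affected")])

  csv <- tempfile()
  writeLines(c("a,0,0,1", "b,0,0,0", "c,a,b,1"), csv)
  expect_equal(genetic_coefficient(read_pedigree(csv), "a", "c"), 0.5)

  bad <- tempfile()
  writeLines("a,0,0", bad)
  expect_error(read_pedigree(bad), "4 fields")
  expect_error(pedigree(data.frame(id = "a", father = "zz", mother = "0",
                                   affected = 0)), "not in pedigree")
})
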