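test_that("read_pedigree parses, validates and flags bad structures", {
  f <- withr::local_tempfile(lines = c("A,0,0", "B,0,0", "C,A,B"))
  ped <- read_pedigree(f)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3)
  expect_equal(ped$sire[ped$animal == "C"], "A")
  expect_equal(ped$dam[ped$animal == "C"], "B")
  expect_true(all(is.na(ped$sire[ped$animal %in% c("A", "B")])))

  expect_error(read_pedigree(data.frame(animal = "A", sire = "A", dam = "0")),
               "own parent")
  expect_error(read_pedigree(data.frame(animal = c("A", "B"),
                                        sire = c("B", "A"),
                                        dam = c("0", "0"))),
               "cycle")
  expect_error(read_pedigree(data.frame(animal = c("A", "A"),
                                        sire = c("0", "0"),
                                        dam = c("0", "0"))),
               "duplicate")
  # referenced-but-undefined parent: promoted with a warning, or an error
  df <- data.frame(animal = "K", sire = "U", dam = "0")
  expect_warning(ped2 <- read_pedigree(df), "founder")
  expect_true("U" %in% ped2$animal)
  expect_error(read_pedigree(df, missing_parent = "error"), "never defined")
})

test_that("sort_pedigree orders parents before offspring, stably", {
  df <- hand_pedigree()[c(6, 4, 5, 1, 2, 3), ]  # offspring listed first
  srt <- sort_pedigree(df)
  pos <- seq_len(nrow(srt)); names(pos) <- srt$animal
  for (i in seq_len(nrow(srt))) {
    if (!is.na(srt$sire[i]) && srt$sire[i] != "0")
      expect_lt(pos[srt$sire[i]], i)
    if (!is.na(srt$dam[i]) && srt$dam[i] != "0")
      expect_lt(pos[srt$dam[i]], i)
  }
  founders <- data.frame(animal = c("z", "a", "m"), sire = NA, dam = NA)
  expect_equal(sort_pedigree(founders)$animal, c("z", "a", "m"))
})

test_that("tabular method reproduces hand-computed relationships", {
  founders <- read_pedigree(data.frame(animal = c("a", "b", "c"),
                                       sire = "0", dam = "0"))
  expect_equal(relationship_matrix(founders),
               diag(3), ignore_attr = TRUE)

  ped <- sort_pedigree(read_pedigree(hand_pedigree()))
  A <- relationship_matrix(ped)
  expect_equal(A["S", "O1"], 0.5)
  expect_equal(A["D", "O1"], 0.5)
  expect_equal(A["O1", "O1"], 1)
  expect_equal(A["O1", "O2"], 0.5)     # full sibs of unrelated parents
  expect_equal(A["X", "X"], 1.0)       # O1 x M are unrelated, no inbreeding
  # offspring of the two full sibs would be inbred: a(i,i) = 1.25
  ped2 <- sort_pedigree(read_pedigree(rbind(
    hand_pedigree(), data.frame(animal = "W", sire = "O1", dam = "O2"))))
  expect_equal(relationship_matrix(ped2)["W", "W"], 1.25)

  expect_error(relationship_matrix(hand_pedigree()[c(4, 1, 2, 3, 5, 6), ]),
               "not sorted")
})

test_that("observation kernel extracts the observed submatrix", {
  ped <- sort_pedigree(read_pedigree(hand_pedigree()))
  A <- relationship_matrix(ped)
  expect_equal(observation_kernel(A, ped$animal), A)
  expect_equal(observation_kernel(A, c("S", "M")), diag(2),
               ignore_attr = TRUE)
  expect_equal(observation_kernel(A, c("S", "O1")),
               matrix(c(1, 0.5, 0.5, 1), 2), ignore_attr = TRUE)
  expect_error(observation_kernel(A, "nope"), "absent")
})

test_that("A is PSD and invariant to record permutation on random pedigrees", {
  for (s in 1:25) {
    ped <- simulate_pedigree(n_founders = 6, n_generations = 2,
                             litter_size = 2, seed = s)
    A <- relationship_matrix(ped)
    expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    expect_true(all(diag(A) >= 1))
    perm <- withr::with_seed(s, sample(nrow(ped)))
    A2 <- relationship_matrix(sort_pedigree(as.data.frame(ped)[perm, ]))
    expect_equal(A2[rownames(A), colnames(A)], A)
  }
})

test_that("tabular A matches the gene-dropping covariance oracle", {
  ped <- simulate_pedigree(n_founders = 8, n_generations = 2,
                           litter_size = 3, seed = 4)
  A <- relationship_matrix(ped)
  u <- simulate_breeding_values(ped, sigma2_a = 2, n_rep = 4e4, seed = 5)
  Ahat <- tcrossprod(u - rowMeans(u)) / (ncol(u) - 1) / 2
  expect_lt(max(abs(Ahat - A)), 0.03)
})
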