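test_that("addition fuses fragments across perimeter bonds", {
  set.seed(1)
  # benzene + benzene can only make naphthalene, whatever the position
  for (i in 1:5) {
    expect_identical(canonical_key(mol_addition(mol$benzene, mol$benzene)),
                     canonical_key(mol$naphthalene))
  }
  # pyridine + pyridine: a two-ring diazine (naphthyridine-type) with both
  # nitrogens intact
  out <- mol_addition(parse_molecule("c1ccncc1"), parse_molecule("c1ccncc1"))
  expect_equal(ring_count(out), 2L)
  expect_equal(n_nitrogens(out), 2L)
})

test_that("forbidden regions exclude peri-fused addition products", {
  pl <- azacene:::addition_placements(mol$anthracene, mol$benzene, forbid = "bay")
  outs <- unique(vapply(pl, function(p) {
    canonical_key(azacene:::new_molecule(p$cells, p$nitro))
  }, character(1)))
  # only the two cata-fused tetracyclics: tetracene and benz[a]anthracene
  expect_length(outs, 2L)
  expect_true(all(vapply(outs, function(s) is_cata_fused(parse_molecule(s)), logical(1))))

  pl2 <- azacene:::addition_placements(mol$anthracene, mol$benzene, forbid = character(0))
  outs2 <- unique(vapply(pl2, function(p) {
    canonical_key(azacene:::new_molecule(p$cells, p$nitro))
  }, character(1)))
  expect_length(outs2, 3L)  # + the pyrene-like peri fill
  expect_true(any(!vapply(outs2, function(s) is_cata_fused(parse_molecule(s)), logical(1))))
})

test_that("addition respects the ring-count cap and signals exhaustion", {
  expect_null(mol_addition(mol$pentacene, mol$benzene, max_rings = 5))
})

test_that("crossover conserves the heavy-atom multiset over all outcomes", {
  a <- parse_molecule("c1ccc2ncccc2c1")
  b <- parse_molecule("n1ccc2ccncc2c1")
  set.seed(42)
  for (i in 1:25) {
    kids <- mol_crossover(a, b, min_rings = 2, max_rings = 2)
    expect_length(kids, 2L)
    expect_equal(sum(vapply(kids, ring_count, integer(1))), 4L)
    expect_equal(sum(vapply(kids, n_nitrogens, integer(1))),
                 n_nitrogens(a) + n_nitrogens(b))
  }
  # self-crossover can reproduce the parent
  set.seed(7)
  seen_parent <- FALSE
  for (i in 1:40) {
    kids <- mol_crossover(a, a, min_rings = 2, max_rings = 2)
    if (any(vapply(kids, canonical_key, character(1)) == canonical_key(a))) {
      seen_parent <- TRUE
      break
    }
  }
  expect_true(seen_parent)
  # single-ring parents cannot be cut
  expect_null(mol_crossover(mol$benzene, mol$benzene))
})

test_that("recombination yields isomers: same formula and ring count", {
  m <- parse_molecule("n1cc2cc3ccccc3cc2cc1")  # an aza-anthracene
  set.seed(3)
  keys <- character(0)
  for (i in 1:30) {
    r <- mol_recombination(m)
    expect_equal(ring_count(r), ring_count(m))
    expect_equal(n_nitrogens(r), n_nitrogens(m))
    keys <- c(keys, canonical_key(r))
  }
  expect_gt(length(unique(keys)), 1L)  # genuinely moves the cut position
  # a 2-ring system has a single cata skeleton: naphthalene maps to itself
  expect_identical(canonical_key(mol_recombination(mol$naphthalene)),
                   canonical_key(mol$naphthalene))
})

test_that("repeated recombination reaches every allowed pentacyclic skeleton", {
  sp <- space_definition()
  skeletons <- unique(enumerate_space(sp, complement_paired = FALSE)$skeleton)
  set.seed(11)
  seen <- canonical_key(mol$pentacene)
  frontier <- list(mol$pentacene)
  for (step in 1:400) {
    m <- resample1(frontier)
    r <- mol_recombination(m)
    k <- canonical_key(r)
    if (!(k %in% seen)) {
      seen <- c(seen, k)
      frontier <- c(frontier, list(r))
    }
    if (length(seen) == length(skeletons)) break
  }
  expect_setequal(seen, skeletons)
})

test_that("mutation swaps single aza sites and leaves unmatched input alone", {
  py <- parse_molecule("c1ccncc1")
  set.seed(5)
  outs <- unique(replicate(80, canonical_key(mol_mutation(py, c("[cH]", "n")))))
  diazines <- vapply(c("c1ccnnc1", "c1cncnc1", "c1cnccn1"), function(s) {
    canonical_key(parse_molecule(s))  # pyridazine, pyrimidine, pyrazine
  }, character(1))
  # all three diazines are reachable; the only other move is N -> CH
  expect_true(all(diazines %in% outs))
  expect_true(all(outs %in% c(diazines, canonical_key(mol$benzene))))
  # each mutation changes exactly one site
  for (i in 1:10) {
    m2 <- mol_mutation(py, c("[cH]", "n"))
    expect_equal(abs(n_nitrogens(m2) - n_nitrogens(py)), 1L)
  }
  # no replacement available -> unchanged
  expect_identical(canonical_key(mol_mutation(py, "n")), canonical_key(py))
  expect_error(mol_mutation(py, "[CX4]"), "unsupported SMARTS")
})

test_that("random molecules are reproducible and inside the size bounds", {
  sp <- space_definition()
  set.seed(99)
  m1 <- random_molecule(sp)
  set.seed(99)
  m2 <- random_molecule(sp)
  expect_identical(canonical_key(m1), canonical_key(m2))
  set.seed(1)
  for (i in 1:10) {
    expect_equal(ring_count(random_molecule(sp)), 5L)
  }
})

test_that("operator outputs stay inside the enumerated space", {
  sp <- space_definition()
  keys <- new.env(parent = emptyenv())
  for (k in enumerate_space(sp, complement_paired = FALSE)$canonical_key) {
    assign(k, TRUE, envir = keys)
  }
  in_space <- function(m) {
    !is.null(get0(canonical_key(m), envir = keys, inherits = FALSE))
  }
  set.seed(17)
  pool <- replicate(12, random_molecule(sp), simplify = FALSE)
  for (i in 1:60) {
    a <- resample1(pool)
    b <- resample1(pool)
    kids <- mol_crossover(a, b, min_rings = 5, max_rings = 5)
    if (!is.null(kids)) for (kid in kids) expect_true(in_space(kid))
    expect_true(in_space(mol_recombination(a)))
    expect_true(in_space(mol_mutation(a, sp$smarts)))
  }
})
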