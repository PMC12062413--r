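# Link-topology generator: constraints, degrees, determinism, and the
# Monte-Carlo degree-distribution check against an independent oracle.

test_that("l_max = 0 and lambda = 0 both force single attachments", {
  g <- small_circle_geom()
  l0 <- generate_links(g, 500, lambda = 50, l_max = 0, seed = 7)
  expect_true(all(link_degrees(l0) == 1L))
  p0 <- generate_links(g, 500, lambda = 0, l_max = 2.5, seed = 7)
  expect_true(all(link_degrees(p0) == 1L))
})

test_that("generation is bit-reproducible for a given seed", {
  g <- small_circle_geom()
  a <- generate_links(g, 800, lambda = 30, l_max = 2.5, seed = 42)
  b <- generate_links(g, 800, lambda = 30, l_max = 2.5, seed = 42)
  expect_identical(a, b)
  c <- generate_links(g, 800, lambda = 30, l_max = 2.5, seed = 43)
  expect_false(identical(a$proximal, c$proximal))
})

test_that("generated links satisfy the structural constraints", {
  g <- small_circle_geom()
  l <- generate_links(g, 2000, lambda = 40, l_max = 2.5, seed = 11)
  expect_true(validate_links(l, g))
  # proximal points uniform over the scar: all inside
  expect_true(all(g$scar[l$proximal]))
})

test_that("generator leaves the global RNG stream untouched", {
  g <- small_circle_geom()
  set.seed(99); before <- .Random.seed
  invisible(generate_links(g, 100, lambda = 10, l_max = 2.5, seed = 5))
  expect_identical(before, .Random.seed)
})

test_that("degree histogram counts hand-built sets exactly", {
  g <- small_circle_geom()
  prox <- rep(pt_of(g, 20, 20), 3)
  links <- manual_links(g, prox,
                        list(integer(), integer(),
                             c(pt_of(g, 21, 20), pt_of(g, 20, 21))))
  h <- degree_histogram(links)
  expect_equal(h$degree, c(1, 2, 3))
  expect_equal(h$fraction, c(2/3, 0, 1/3))
  expect_equal(sum(h$fraction), 1)
  all1 <- manual_links(g, prox, rep(list(integer()), 3))
  expect_equal(degree_histogram(all1)$fraction, 1)
})

test_that("inverting links is an exact inverse (handshake identity)", {
  g <- small_circle_geom()
  a <- pt_of(g, 18, 20); b <- pt_of(g, 22, 20)
  one <- manual_links(g, pt_of(g, 20, 20), list(c(a, b)))
  inv <- invert_links(one, g)
  expect_equal(inv[[a]], 1L)
  expect_equal(inv[[b]], 1L)
  expect_equal(inv[[pt_of(g, 20, 20)]], 1L)
  expect_equal(sum(lengths(inv)), sum(link_degrees(one)))

  rnd <- generate_links(g, 1500, lambda = 30, l_max = 2.5, seed = 3)
  inv2 <- invert_links(rnd, g)
  expect_equal(sum(lengths(inv2)), sum(link_degrees(rnd)))
  # round trip: rebuild unit attachment sets from the inverse map
  rebuilt <- vector("list", rnd$n_units)
  for (p in which(lengths(inv2) > 0))
    for (u in inv2[[p]]) rebuilt[[u]] <- c(rebuilt[[u]], p)
  for (u in seq_len(rnd$n_units))
    expect_setequal(rebuilt[[u]], c(rnd$proximal[u], rnd$distal[[u]]))
})

test_that("multi-attachment fraction grows with lambda and l_max", {
  g <- small_circle_geom()
  frac_multi <- function(lambda, l_max) {
    f <- vapply(1:6, function(s) {
      l <- generate_links(g, 600, lambda = lambda, l_max = l_max, seed = s)
      mean(link_degrees(l) > 1)
    }, numeric(1))
    mean(f)
  }
  by_lambda <- vapply(c(10, 30, 60), frac_multi, numeric(1), l_max = 2.5)
  expect_true(all(diff(by_lambda) >= 0))
  by_lmax <- vapply(c(0, 1.25, 2.5), function(lm) frac_multi(50, lm),
                    numeric(1))
  expect_true(all(diff(by_lmax) >= 0))
})

test_that("degree distribution matches an independent Monte-Carlo oracle", {
  g <- small_circle_geom()
  n <- 1e5; lambda <- 20; l_max <- 2.5
  links <- generate_links(g, n, lambda = lambda, l_max = l_max, seed = 101)
  got <- tabulate(link_degrees(links), nbins = 12)

  # oracle: direct simulation of the definition, independent code path
  set.seed(2024)
  scar_idx <- which(g$scar)
  npts <- g$nx * g$ny
  ij <- cbind(((seq_len(npts) - 1) %% g$nx) + 1,
              ((seq_len(npts) - 1) %/% g$nx) + 1)
  prox <- sample(scar_idx, n, replace = TRUE)
  k <- rpois(n, lambda)
  deg <- integer(n)
  cand_all <- sample.int(npts, sum(k), replace = TRUE)
  off <- c(0, cumsum(k))
  for (u in seq_len(n)) {
    if (k[u] == 0) { deg[u] <- 1L; next }
    cand <- cand_all[(off[u] + 1):off[u + 1]]
    d <- g$dx * sqrt((ij[cand, 1] - ij[prox[u], 1])^2 +
                     (ij[cand, 2] - ij[prox[u], 2])^2)
    keep <- unique(cand[d <= l_max])
    deg[u] <- 1L + sum(keep != prox[u])
  }
  want <- tabulate(deg, nbins = 12)

  # multinomial 3-sigma comparison per degree bin (pooled proportions)
  for (b in seq_len(12)) {
    p <- (got[b] + want[b]) / (2 * n)
    if (p == 0) next
    sd3 <- 3 * sqrt(2 * n * p * (1 - p))
    expect_lt(abs(got[b] - want[b]), max(sd3, 12))
  }
})

test_that("generator input validation", {
  g <- small_circle_geom()
  expect_error(generate_links(tiny_geom(), 10, 5, 2.5, seed = 1),
               "no scar")
  expect_error(generate_links(g, 10, lambda = -1, l_max = 2.5, seed = 1),
               "lambda")
  expect_error(generate_links(g, 10, lambda = 5, l_max = -0.5, seed = 1),
               "l_max")
})

test_that("realisation ids map to fixed documented seeds", {
  expect_identical(realisation_seed(1:5), as.integer(202501:202505))
  expect_error(realisation_seed(0), "positive")
})
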