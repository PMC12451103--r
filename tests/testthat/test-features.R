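test_that("conservation scores match the closed-form entropy cases", {
  # fully conserved column -> H = 0 -> score 1; uniform column -> H = 2 ->
  # score 0; half/half column -> H = 1 -> score 0.5
  fa <- paste0(">q\nAAA\n>r1\nAUA\n>r2\nAGU\n>r3\nACU\n")
  msa <- read_msa(fa, "q")
  sc <- conservation_scores(msa)
  expect_equal(sc[1], 1.0)
  expect_equal(sc[2], 0.0)
  expect_equal(sc[3], 0.5)
})

test_that("conservation is permutation-invariant to MSA row order and
           gap-only columns warn", {
  set.seed(4)
  rows <- replicate(6, paste(sample(c("A", "C", "G", "U", "-"), 10,
                                    replace = TRUE), collapse = ""))
  rows[1] <- "ACGUACGUAC"
  fa <- paste(sprintf(">s%d\n%s", seq_along(rows), rows), collapse = "\n")
  sc1 <- conservation_scores(read_msa(fa, "s1"))
  fa2 <- paste(sprintf(">s%d\n%s", c(1, 4, 3, 2, 6, 5),
                       rows[c(1, 4, 3, 2, 6, 5)]), collapse = "\n")
  sc2 <- conservation_scores(read_msa(fa2, "s1"))
  expect_equal(sc1, sc2)
  expect_true(all(sc1 >= 0 & sc1 <= 1))
  # query-only column scores 0 with a warning
  lone <- ">q\nAA\n>r\nA-\n"
  expect_warning(sc3 <- conservation_scores(read_msa(lone, "q")),
                 "besides the query")
  expect_equal(sc3[2], 0)
})

test_that("one-hot channel order is (A, U, G, C)", {
  oh <- one_hot_encode(c("A", "C", "other", "U", "G"))
  expect_equal(oh[1, ], c(A = 1, U = 0, G = 0, C = 0))
  expect_equal(oh[2, ], c(A = 0, U = 0, G = 0, C = 1))
  expect_equal(sum(oh[3, ]), 0)
})

test_that("secondary feature block has degree plus four presence flags", {
  ann <- read_secondary_annotation(
    "2 7 canonical_pair\n3 6 base_phosphate\nloop 4 5", 8L)
  sf <- secondary_feature_vector(ann)
  # interior nucleotide with one canonical pair: 2 backbone + 1 pair = 3
  expect_equal(sf[2, "degree"], 3, ignore_attr = TRUE)
  expect_equal(unname(sf[2, 2:5]), c(0, 0, 0, 0))
  # chain end with no interactions: one backbone neighbour
  expect_equal(sf[1, "degree"], 1, ignore_attr = TRUE)
  # base-phosphate flag set on both partners
  expect_equal(sf[3, "base_phosphate"], 1, ignore_attr = TRUE)
  expect_equal(sf[6, "base_phosphate"], 1, ignore_attr = TRUE)
  expect_equal(sf[4, "loop"], 1, ignore_attr = TRUE)
})

test_that("topological properties match closed forms on K3 and the star", {
  tri <- topological_properties(rbind(c(0, 1), c(0, 2), c(1, 2)), 3L)
  expect_equal(unname(tri[1, ]), c(2, 2, 0, 1, 1))
  path <- topological_properties(rbind(c(0, 1), c(1, 2)), 3L)
  expect_equal(path[2, "betweenness"], 1, ignore_attr = TRUE)  # the single (0,2) pair
  expect_equal(path[2, "clustering"], 0, ignore_attr = TRUE)
  expect_equal(path[2, "eccentricity"], 1, ignore_attr = TRUE)
  star <- topological_properties(cbind(0L, 1:4), 5L)
  expect_equal(star[1, "nbr_connectivity"], 1, ignore_attr = TRUE)  # all leaves have degree 1
  expect_error(topological_properties(matrix(integer(0), ncol = 2), 0L),
               "n = 0")
})

test_that("topological properties agree with path-enumeration oracle on
           random graphs", {
  set.seed(9)
  for (rep in 1:25) {
    n <- sample(2:7, 1)
    edges <- random_graph(n)
    expect_equal(topological_properties(edges, n), oracle_topology(edges, n),
                 tolerance = 1e-12)
  }
})

test_that("assemble_features lays blocks out with stable width", {
  n <- 6L
  oh <- one_hot_encode(rep("A", n))
  sec <- matrix(0, n, 5)
  topo <- matrix(1, n, 5)
  full <- assemble_features(oh, sec, topo, conservation = runif(n),
                            embeddings = matrix(0, n, 120), asa = rnorm(n))
  expect_equal(ncol(full$X), 1 + 120 + 4 + 5 + 5 + 1)
  # omitted optional blocks keep the width and are recorded
  part <- assemble_features(oh, sec, topo, d_emb = 120)
  expect_equal(ncol(part$X), 136)
  expect_false(part$provided[["embedding"]])
  expect_true(all(part$X[, part$block_map$embedding] == 0))
  expect_error(assemble_features(oh, sec[1:5, ], topo), "secondary")
})

test_that("block map slicing recovers inputs; z-scoring only touches
           continuous columns", {
  set.seed(2)
  n <- 10L
  oh <- one_hot_encode(sample(c("A", "C", "G", "U"), n, replace = TRUE))
  sec <- cbind(rpois(n, 2), matrix(rbinom(4 * n, 1, 0.3), n))
  topo <- matrix(rnorm(5 * n), n)
  cons <- runif(n)
  raw <- assemble_features(oh, sec, topo, conservation = cons,
                           embeddings = matrix(rnorm(3 * n), n),
                           asa = rnorm(n))
  expect_equal(raw$X[, raw$block_map$one_hot], unname(oh))
  expect_equal(raw$X[, raw$block_map$secondary], unname(sec))
  st <- feature_stats(list(raw))
  std <- standardize_features(raw, st)
  # flags untouched
  expect_equal(std$X[, std$block_map$one_hot], unname(oh))
  expect_equal(std$X[, std$block_map$secondary[2:5]], unname(sec[, 2:5]))
  # continuous columns are the z-scored image of the raw block
  expect_equal(std$X[, std$block_map$conservation],
               (cons - mean(cons)) / sd(cons))
})

test_that("zero_feature_block blanks exactly the requested view", {
  g <- tiny_mvg(6L, seed = 2)
  z <- zero_feature_block(g$x_init, "ter")
  map <- z$block_map
  expect_true(all(z$X[, c(map$topological, map$asa)] == 0))
  expect_equal(z$X[, map$one_hot], g$x_init$X[, map$one_hot])
  expect_error(zero_feature_block(g$x_init, "quaternary"), "unknown view")
})

test_that("geometric accessibility proxy scores exposed residues higher", {
  # a tight cluster of 3 points plus one distant point: the distant point
  # has no neighbours within 8 A and the largest (least negative) score
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(50, 0, 0))
  v <- asa_geometric_proxy(pts)
  expect_equal(v, c(-2, -2, -2, 0))
  expect_equal(which.max(v), 4L)
  expect_error(asa_geometric_proxy(rbind(c(0, 0, NA))), "is.finite")
})
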