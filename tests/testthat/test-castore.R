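test_that("the parse of a constant quadruple follows the pair-coding rule", {
  ev <- castore_parse(symbolic_string(rep(1L, 4), 2))
  # step 1: empty prefix + literal 1; step 2: "1" + "1" -> "11";
  # step 3: terminal event with empty suffix
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$prefix, c(0L, 1L, 1L))
  expect_equal(ev$suffix_type, c("literal", "word", "none"))
  expect_equal(sum(ev$word_length), 4L) # every symbol consumed once
  expect_equal(ev$new_word_index, 1:3)

  one <- castore_parse(symbolic_string(1L, 2))
  expect_equal(nrow(one), 1L)
  expect_equal(one$prefix, 0L)
  expect_equal(one$suffix_type, "literal")
})

test_that("decoding inverts parsing", {
  ev <- castore_parse(symbolic_string(rep(1L, 4), 2))
  expect_equal(as.integer(castore_decode(ev)), rep(1L, 4))

  withr::with_seed(101, {
    for (i in 1:60) {
      a <- sample(2:20, 1)
      s <- random_string(sample(1:500, 1), a)
      expect_identical(as.integer(castore_decode(castore_parse(s))),
                       as.integer(s))
    }
  })

  expect_error(castore_decode(castore_parse(symbolic_string(1:3, 3))[0, ],
                              alphabet_size = 3),
               class = "mkse_corrupt_parse")
  # dangling word index
  bad <- castore_parse(symbolic_string(c(1L, 1L, 1L, 1L), 2))
  bad$suffix[bad$suffix_type == "word"] <- 99L
  expect_error(castore_decode(bad), class = "mkse_corrupt_parse")
})

test_that("compressed length follows the index + flag + suffix cost model", {
  # single event, empty prefix, literal over alphabet 2: 0 + 1 + 1 bits
  expect_equal(compressed_length(castore_parse(symbolic_string(1L, 2))), 2)
  # frozen hand computation for the constant quadruple:
  # event 1 (m=1): 0+1+1; event 2 (m=2): 1+1+1; terminal (m=3): 2+1+0
  expect_equal(compressed_length(castore_parse(symbolic_string(rep(1L, 4),
                                                               2))), 8)
  # additive over events given the dictionary state
  ev <- withr::with_seed(55, castore_parse(random_string(300, 4)))
  ceil_log2 <- function(k) ifelse(k <= 1, 0, ceiling(log2(k)))
  manual <- sum(ceil_log2(seq_len(nrow(ev))) + 1 +
                  ifelse(ev$suffix_type == "word",
                         ceil_log2(seq_len(nrow(ev))),
                         ifelse(ev$suffix_type == "literal", 2, 0)))
  expect_equal(compressed_length(ev), manual)
})

test_that("regular strings compress sublinearly", {
  const <- function(n) symbolic_string(rep(1L, n), 2)
  bits <- function(s) compressed_length(castore_parse(s))
  b4096 <- bits(const(4096))
  expect_lt(b4096 / 4096, 0.1)
  # doubling the length less than doubles the compressed size
  expect_lt(bits(const(8192)), 2 * b4096)
  per <- generate_symbolic("periodic", length = 10000, alphabet_size = 2)
  expect_lt(estimate_entropy_rate(per), 0.1)
})

test_that("entropy-rate estimates order sources by predictability", {
  withr::with_seed(202, {
    n <- 10000
    e_const <- estimate_entropy_rate(
      generate_symbolic("constant", n, alphabet_size = 2))
    e_per <- estimate_entropy_rate(
      generate_symbolic("periodic", n, alphabet_size = 2))
    e_iid <- estimate_entropy_rate(generate_symbolic("iid", n, 2))
    expect_lt(e_const, e_per)
    expect_lt(e_per, e_iid)
    expect_gte(e_const, 0)
  })
})

test_that("the estimate approaches the analytic rate from above as length grows", {
  P <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  h <- attr(generate_symbolic("markov", 10, transition = P, seed = 1),
            "analytic_rate")
  expect_equal(h, 0.4690, tolerance = 1e-4) # closed form, pi = (1/2, 1/2)
  e4 <- estimate_entropy_rate(
    generate_symbolic("markov", 1e4, transition = P, seed = 31))
  e5 <- estimate_entropy_rate(
    generate_symbolic("markov", 1e5, transition = P, seed = 31))
  expect_lt(abs(e5 - h), abs(e4 - h)) # relative error shrinks with length

  # i.i.d. envelope: the compression estimate exceeds the marginal Shannon
  # entropy by a coder overhead that shrinks with length
  s4 <- generate_symbolic("iid", 1e4, 2, seed = 7)
  s5 <- generate_symbolic("iid", 1e5, 2, seed = 7)
  over4 <- estimate_entropy_rate(s4) - shannon_entropy(s4)
  over5 <- estimate_entropy_rate(s5) - shannon_entropy(s5)
  expect_gt(over4, 0)
  expect_lt(over5, over4)
})

test_that("short strings warn but still return an estimate", {
  s <- random_string(200, 2)
  expect_warning(r <- estimate_entropy_rate(s), class = "mkse_short_string")
  expect_gte(r, 0)
  expect_error(estimate_entropy_rate(integer(0), alphabet_size = 2),
               class = "mkse_empty_string")
  expect_error(castore_parse(c(1L, 5L), alphabet_size = 2))
})
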