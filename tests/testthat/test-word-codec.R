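lib <- make_token_library(8, seed = 11)

test_that("token library honours length, distance and composition constraints", {
  expect_length(lib$tokens, 8L)
  expect_true(all(nchar(lib$tokens) == 20L))
  for (i in 1:7) for (j in (i + 1):8)
    expect_gte(hamming_dist(lib$tokens[i], lib$tokens[j]), 8L)
  gc <- vapply(strsplit(lib$tokens, ""),
               function(s) mean(s %in% c("C", "G")), numeric(1))
  expect_true(all(gc >= 0.4 & gc <= 0.6))
  expect_identical(make_token_library(8, seed = 11)$tokens, lib$tokens)
})

test_that("word encoding is deterministic with closed-form strand length", {
  s1 <- encode_word("A", token5 = 1, token3 = 2, library = lib)
  s2 <- encode_word("A", token5 = 1, token3 = 2, library = lib)
  expect_identical(s1$sequence, s2$sequence)
  # by-hand bit accounting for "We": (1 length byte + 2 chars) * 8 = 24 bits,
  # padded to 27 = 3 RS(7,3) blocks of 9 message bits, 3 * 21 = 63 codeword
  # bits, padded to 64 = 32 payload nt, plus two 20-nt tokens = 72 nt
  s <- encode_word("We", token5 = 1, token3 = 2, library = lib)
  expect_identical(nchar(s$payload), 32L)
  expect_identical(nchar(s$sequence), 72L)
  expect_error(encode_word("", token5 = 1, token3 = 2, library = lib),
               "non-empty")
  expect_error(encode_word("café", token5 = 1, token3 = 2, library = lib),
               "ASCII")
})

test_that("assembly shares each junction token exactly once and flags mismatches", {
  st <- encode_sentence(c("We", "love", "DNA."), lib)
  single <- assemble(st[1], lib)
  expect_identical(single, st[[1]]$sequence)
  two <- assemble(st[1:2], lib)
  expect_identical(nchar(two),
                   nchar(st[[1]]$sequence) + nchar(st[[2]]$sequence) - 20L)
  all3 <- assemble(st, lib)
  expect_identical(nchar(all3), sum(vapply(st, function(s)
    nchar(s$sequence), integer(1))) - 2L * 20L)
  broken <- st
  broken[[3]] <- encode_word("DNA.", token5 = 7, token3 = 8, library = lib)
  expect_error(assemble(broken, lib), "junction 3")
})

test_that("token identification matches the sliding DP oracle", {
  with_seed(4, {
    for (rep in 1:10) {
      tok_id <- sample(1:8, 1)
      tok <- lib$tokens[tok_id]
      pre <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                   collapse = "")
      post <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                    collapse = "")
      # corrupt 0-2 positions of the embedded token
      tk <- strsplit(tok, "")[[1]]
      nmut <- sample(0:2, 1)
      if (nmut > 0) {
        at <- sample(20, nmut)
        tk[at] <- vapply(tk[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      }
      seqn <- paste0(pre, paste(tk, collapse = ""), post)
      hits <- identify_tokens(seqn, lib)
      hit <- hits[hits$token_id == tok_id, ]
      expect_identical(nrow(hit), 1L)
      expect_equal(hit$score, oracle_semiglobal_score(tok, seqn))
      if (nmut == 0) {
        expect_identical(hit$offset, 26L)
        expect_equal(hit$score, 20)
      }
    }
  })
})

test_that("no token is reported on unrelated random sequence", {
  rnd <- with_seed(9, paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                            collapse = ""))
  hits <- identify_tokens(rnd, lib)
  expect_identical(nrow(hits), 0L)
})

test_that("sentence round trip is identity under zero noise", {
  st <- encode_sentence(c("We", "love", "DNA."), lib)
  expect_identical(decode_words(assemble(st, lib), lib),
                   c("We", "love", "DNA."))
  # random printable words up to length 12
  with_seed(6, {
    for (rep in 1:5) {
      words <- vapply(1:3, function(i)
        rawToChar(as.raw(sample(33:126, sample(1:12, 1), replace = TRUE))),
        character(1))
      st <- encode_sentence(words, lib)
      expect_identical(decode_words(assemble(st, lib), lib), words)
    }
  })
})

test_that("payload errors within the RS radius are transparent; beyond it the word is NA", {
  st <- encode_sentence(c("We", "love", "DNA."), lib)
  sent <- assemble(st, lib)
  # substitute 2 bases inside one payload codeword (<= t = 2 symbol errors)
  ch <- strsplit(sent, "")[[1]]
  at <- 20L + 3L   # inside the first word payload
  for (p in c(at, at + 1L))
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  expect_identical(decode_words(paste(ch, collapse = ""), lib),
                   c("We", "love", "DNA."))
  # an empty inter-token region decodes as unrecovered
  two_tokens <- paste0(lib$tokens[1], lib$tokens[2])
  expect_identical(decode_words(two_tokens, lib), NA_character_)
})
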