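test_that("JSONL corpus round trip preserves all fields and document order", {
  corp <- tiny_corpus(n_per = 1, length_mean = 15)
  corp2 <- handmade_corpus()
  corp2$tags[2] <- list(NULL)
  corp2$annotation_source[2] <- "none"
  both <- dplyr::bind_rows(corp, corp2)
  both <- validate_corpus(both)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(both, path)
  back <- read_corpus(path)
  expect_equal(back$id, both$id)
  expect_equal(back$label, both$label)
  expect_equal(back$task, both$task)
  expect_equal(back$tokens, both$tokens)
  expect_equal(back$annotation_source, both$annotation_source)
  for (i in seq_len(nrow(both))) {
    if (is.null(both$tags[[i]])) expect_null(back$tags[[i]])
    else expect_equal(unname(back$tags[[i]]), unname(both$tags[[i]]))
  }
})

test_that("empty corpus file reads as an empty dataset", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), path)
  expect_equal(nrow(read_corpus(path)), 0L)
})

test_that("malformed corpus records fail with line or document identity", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"id":"ok","label":"AS","task":"interview","tokens":["a"]}',
               "{not json"), path)
  expect_error(read_corpus(path), "line 2")

  # tag matrix with L-1 rows
  writeLines(paste0('{"id":"short","label":"AS","task":"interview",',
                    '"tokens":["a","b"],"tags":[[]]}'), path)
  expect_error(read_corpus(path), "short")

  corp <- handmade_corpus()
  corp$tags[[1]] <- corp$tags[[1]][-1, , drop = FALSE]
  expect_error(validate_corpus(corp), "d1")
})

test_that("token table uses '|' joins and '_' and round-trips exactly", {
  corp <- handmade_corpus()
  tab <- to_token_table(corp)
  expect_equal(tab$tags[tab$doc_id == "d1"][2],
               "modality.ability|filler.maa")
  expect_equal(tab$tags[tab$doc_id == "d1"][3], "_")
  meta <- corp[, c("id", "label", "task", "annotation_source")]
  back <- from_token_table(tab, meta = meta)
  expect_equal(back$tokens, corp$tokens)
  expect_equal(lapply(back$tags, unname), lapply(corp$tags, unname))
  expect_equal(back$label, corp$label)
})

test_that("unknown tag names in a token table are rejected with the row", {
  tab <- tibble::tibble(doc_id = "d", token_index = 1:2,
                        token = c("a", "b"), tags = c("_", "no.such_tag"))
  expect_error(from_token_table(tab), "row 2")
})

test_that("tag frequencies follow the count-over-length definition", {
  corp <- handmade_corpus()
  fr <- tag_frequencies(corp)
  expect_equal(fr$n_tokens, c(4L, 3L))
  expect_equal(fr[["modality.ability"]], c(0.5, 0))
  expect_equal(fr[["filler.maa"]], c(0.25, 0))
  # all-zero matrix gives the zero vector; all-active tag gives 1
  expect_true(all(as.matrix(fr[2, schema$name]) == 0))
  corp$tags[[2]][, tag_index(schema, "filler.ano") + 1] <- 1L
  fr2 <- tag_frequencies(corp)
  expect_equal(fr2[["filler.ano"]][2], 1.0)
})

test_that("tag frequencies are invariant to token order and sum to cell count", {
  corp <- tiny_corpus(n_per = 2, length_mean = 40)
  fr <- tag_frequencies(corp)
  perm <- withr::with_seed(5, sample(length(corp$tokens[[1]])))
  corp2 <- corp
  corp2$tokens[[1]] <- corp2$tokens[[1]][perm]
  corp2$tags[[1]] <- corp2$tags[[1]][perm, , drop = FALSE]
  fr2 <- tag_frequencies(corp2)
  expect_equal(as.matrix(fr2[, schema$name]), as.matrix(fr[, schema$name]))
  # sum over tags of value_i * L equals total active cells
  for (i in seq_len(nrow(corp))) {
    expect_equal(sum(fr[i, schema$name]) * fr$n_tokens[i],
                 sum(corp$tags[[i]]))
  }
})

test_that("tag_frequencies requires tag matrices", {
  corp <- handmade_corpus()
  corp$tags[1] <- list(NULL)
  corp$annotation_source[1] <- "none"
  expect_error(tag_frequencies(corp), "d1")
})
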