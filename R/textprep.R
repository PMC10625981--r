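#' The package's frozen Italian stop-word list
#'
#' A plain-text list of Italian function words (articles, prepositions,
#' articulated prepositions, pronouns, and the conjugations of essere, avere,
#' fare and stare) shipped with the package so that preprocessing is fully
#' reproducible.
#'
#' @return Character vector of stop words.
#' @export
italian_stopwords <- function() {
  path <- system.file("extdata", "italian_stopwords.txt", package = "cvdnotes")
  readLines(path, encoding = "UTF-8")
}

# ---- Snowball Italian stemmer ------------------------------------------------
# Implementation of the Snowball stemming algorithm for Italian: acute accents
# normalised to grave, u-after-q and intervocalic i/u marked as consonants,
# R1/R2/RV regions, attached-pronoun removal, standard and verb suffix
# removal, final-vowel deletion.

.it_vowels <- c("a", "e", "i", "o", "u", "à", "è", "ì",
                "ò", "ù")

.it_pronouns <- c("gliela", "gliele", "glieli", "glielo", "gliene",
                  "sene", "mela", "mele", "meli", "melo", "mene",
                  "tela", "tele", "teli", "telo", "tene",
                  "cela", "cele", "celi", "celo", "cene",
                  "vela", "vele", "veli", "velo", "vene",
                  "gli", "ci", "la", "le", "li", "lo", "mi", "ne", "si",
                  "ti", "vi")

.it_step2_suffixes <- c(
  "erebbero", "irebbero", "assero", "assimo", "eranno", "erebbe", "eremmo",
  "ereste", "eresti", "essero", "iranno", "irebbe", "iremmo", "ireste",
  "iresti", "iscano", "iscono", "issero", "arono", "avamo", "avano", "avate",
  "eremo", "erete", "erono", "evamo", "evano", "evate", "iremo", "irete",
  "irono", "ivamo", "ivano", "ivate", "ammo", "ando", "asse", "assi", "emmo",
  "enda", "ende", "endi", "endo", "erai", "erei", "Iamo", "iamo", "immo",
  "irai", "irei", "isca", "isce", "isci", "isco", "ano", "are", "ata", "ate",
  "ati", "ato", "ava", "avi", "avo", "erà", "ere", "erò", "ete",
  "eva", "evi", "evo", "irà", "ire", "irò", "ita", "ite", "iti",
  "ito", "iva", "ivi", "ivo", "ono", "uta", "ute", "uti", "uto", "ar", "ir")

# step-1 standard suffixes: name = suffix, value = region rule
.it_step1 <- list(
  r2_delete = c("atrice", "atrici", "anza", "anze", "iche", "ichi", "ismo",
                "ismi", "abile", "abili", "ibile", "ibili", "ista", "iste",
                "isti", "istà", "istè", "istì", "oso", "osi",
                "osa", "ose", "mente", "ante", "anti", "ico", "ici", "ica",
                "ice"),
  r2_azione = c("azione", "azioni", "atore", "atori"),
  r2_logia = c("logia", "logie"),
  r2_uzione = c("uzione", "uzioni", "usione", "usioni"),
  r2_enza = c("enza", "enze"),
  rv_amento = c("amento", "amenti", "imento", "imenti"),
  r1_amente = "amente",
  r2_ita = "ità",
  r2_ivo = c("ivo", "ivi", "iva", "ive")
)

.first_nonvowel_after_vowel <- function(is_v, start) {
  n <- length(is_v)
  k <- start + 1L
  while (k <= n) {
    if (is_v[k - 1L] && !is_v[k]) return(k + 1L)
    k <- k + 1L
  }
  n + 1L
}

.it_regions <- function(chars, is_v) {
  n <- length(chars)
  r1 <- .first_nonvowel_after_vowel(is_v, 1L)
  r2 <- .first_nonvowel_after_vowel(is_v, r1)
  rv <- n + 1L
  if (n >= 2L) {
    if (!is_v[2L]) {
      k <- 3L
      while (k <= n && !is_v[k]) k <- k + 1L
      if (k <= n) rv <- k + 1L
    } else if (is_v[1L] && is_v[2L]) {
      k <- 3L
      while (k <= n && is_v[k]) k <- k + 1L
      if (k <= n) rv <- k + 1L
    } else {
      if (n >= 3L) rv <- 4L
    }
  }
  list(r1 = r1, r2 = r2, rv = rv)
}

.longest_suffix <- function(word, suffixes) {
  hit <- suffixes[endsWith(word, suffixes)]
  if (length(hit) == 0) return(NULL)
  hit[which.max(nchar(hit))]
}

# suffix position (index of its first character) lies inside a region?
.suffix_in <- function(word, suffix, region_start) {
  nchar(word) - nchar(suffix) + 1L >= region_start
}

.drop_suffix <- function(word, suffix) {
  substr(word, 1L, nchar(word) - nchar(suffix))
}

.stem_it_one <- function(word) {
  word <- chartr("áéíóú", "àèìòù", word)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(word)
  orig_v <- chars %in% .it_vowels
  for (j in seq_len(n)) {
    if (chars[j] == "u" && j > 1L && chars[j - 1L] == "q") {
      chars[j] <- "U"
    } else if (chars[j] %in% c("i", "u") && j > 1L && j < n &&
               orig_v[j - 1L] && orig_v[j + 1L]) {
      chars[j] <- toupper(chars[j])
    }
  }
  word <- paste(chars, collapse = "")
  is_v <- chars %in% .it_vowels
  rg <- .it_regions(chars, is_v)

  # step 0: attached pronouns
  pron <- .longest_suffix(word, .it_pronouns)
  if (!is.null(pron)) {
    rest <- .drop_suffix(word, pron)
    ger <- .longest_suffix(rest, c("ando", "endo"))
    inf <- .longest_suffix(rest, c("ar", "er", "ir"))
    if (!is.null(ger) && .suffix_in(rest, ger, rg$rv)) {
      word <- rest
    } else if (!is.null(inf) && .suffix_in(rest, inf, rg$rv)) {
      word <- paste0(rest, "e")
    }
  }

  # step 1: standard suffixes (longest match wins; its condition decides)
  step1_done <- FALSE
  all_s1 <- unlist(.it_step1, use.names = FALSE)
  suf <- .longest_suffix(word, all_s1)
  if (!is.null(suf)) {
    if (suf %in% .it_step1$r1_amente) {
      if (.suffix_in(word, suf, rg$r1)) {
        word <- .drop_suffix(word, suf)
        step1_done <- TRUE
        if (endsWith(word, "iv") && .suffix_in(word, "iv", rg$r2)) {
          word <- .drop_suffix(word, "iv")
          if (endsWith(word, "at") && .suffix_in(word, "at", rg$r2)) {
            word <- .drop_suffix(word, "at")
          }
        } else {
          for (s2 in c("abil", "os", "ic")) {
            if (endsWith(word, s2) && .suffix_in(word, s2, rg$r2)) {
              word <- .drop_suffix(word, s2)
              break
            }
          }
        }
      }
    } else if (suf %in% .it_step1$rv_amento) {
      if (.suffix_in(word, suf, rg$rv)) {
        word <- .drop_suffix(word, suf)
        step1_done <- TRUE
      }
    } else if (.suffix_in(word, suf, rg$r2)) {
      if (suf %in% .it_step1$r2_logia) {
        word <- paste0(.drop_suffix(word, suf), "log")
      } else if (suf %in% .it_step1$r2_uzione) {
        word <- paste0(.drop_suffix(word, suf), "u")
      } else if (suf %in% .it_step1$r2_enza) {
        word <- paste0(.drop_suffix(word, suf), "ente")
      } else {
        word <- .drop_suffix(word, suf)
        if (suf %in% .it_step1$r2_azione &&
            endsWith(word, "ic") && .suffix_in(word, "ic", rg$r2)) {
          word <- .drop_suffix(word, "ic")
        }
        if (suf %in% .it_step1$r2_ita) {
          for (s2 in c("abil", "ic", "iv")) {
            if (endsWith(word, s2) && .suffix_in(word, s2, rg$r2)) {
              word <- .drop_suffix(word, s2)
              break
            }
          }
        }
        if (suf %in% .it_step1$r2_ivo &&
            endsWith(word, "at") && .suffix_in(word, "at", rg$r2)) {
          word <- .drop_suffix(word, "at")
          if (endsWith(word, "ic") && .suffix_in(word, "ic", rg$r2)) {
            word <- .drop_suffix(word, "ic")
          }
        }
      }
      step1_done <- TRUE
    }
  }

  # step 2: verb suffixes, only if step 1 left the word unchanged
  if (!step1_done) {
    suf <- .longest_suffix(word, .it_step2_suffixes)
    if (!is.null(suf) && .suffix_in(word, suf, rg$rv)) {
      word <- .drop_suffix(word, suf)
    }
  }

  # step 3a: final vowel (and a preceding i) in RV
  last <- substr(word, nchar(word), nchar(word))
  if (last %in% c("a", "e", "i", "o", "à", "è", "ì", "ò") &&
      nchar(word) >= rg$rv) {
    word <- substr(word, 1L, nchar(word) - 1L)
    if (substr(word, nchar(word), nchar(word)) %in% c("i", "I") &&
        nchar(word) >= rg$rv) {
      word <- substr(word, 1L, nchar(word) - 1L)
    }
  }
  # step 3b: ch -> c, gh -> g in RV
  if ((endsWith(word, "ch") || endsWith(word, "gh")) &&
      .suffix_in(word, "ch", rg$rv)) {
    word <- substr(word, 1L, nchar(word) - 1L)
  }
  chartr("IU", "iu", word)
}

#' Stem Italian words (Snowball algorithm)
#'
#' @param words character vector of lowercase words.
#' @return Character vector of stems, same length as `words`.
#' @export
stem_italian <- function(words) {
  if (length(words) == 0) return(character(0))
  uq <- unique(words)
  stems <- vapply(uq, .stem_it_one, character(1), USE.NAMES = FALSE)
  stems[match(words, uq)]
}

#' Clean and stem free-form visit text
#'
#' Applies the fixed preprocessing order: lowercase, whitespace tokenisation,
#' stop-word removal, then stemming. Rare-token pruning happens later, at
#' vocabulary construction, and the minimum-length filter at encoding.
#'
#' @param texts character vector of notes.
#' @param stopwords character vector; removed before stemming.
#' @return List of character vectors (one token vector per note; possibly
#'   empty).
#' @export
clean_and_stem <- function(texts, stopwords = italian_stopwords()) {
  toks <- strsplit(stringr::str_to_lower(texts), "\\s+")
  purrr::map(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    tk <- tk[!tk %in% stopwords]
    stem_italian(tk)
  })
}

#' Build a token vocabulary from the training corpus
#'
#' Tokens are ranked by corpus frequency; the lowest-frequency tokens making
#' up the bottom `prune_fraction` of the distinct-token list (i.e.
#' `ceiling(prune_fraction * n_distinct)` types, ties broken lexicographically)
#' are removed. Remaining tokens are indexed by descending frequency starting
#' at 2; index 0 is reserved for padding and 1 for out-of-vocabulary tokens.
#'
#' @param corpus_tokens list of token vectors from the *training split only*.
#' @param prune_fraction fraction of distinct tokens to prune (default 1%).
#' @return A tibble of class `cvd_vocab` with columns `token`, `index`,
#'   `freq` (corpus frequency) and `doc_freq` (number of notes containing the
#'   token).
#' @export
build_vocabulary <- function(corpus_tokens, prune_fraction = 0.01) {
  stopifnot(prune_fraction >= 0, prune_fraction < 1)
  all_tokens <- unlist(corpus_tokens, use.names = FALSE)
  if (length(all_tokens) == 0) {
    abort("Empty corpus: cannot build a vocabulary.", class = "cvdnotes_config_error")
  }
  freq <- table(all_tokens)
  doc_freq <- table(unlist(lapply(corpus_tokens, unique), use.names = FALSE))
  tab <- tibble::tibble(token = names(freq), freq = as.integer(freq))
  tab$doc_freq <- as.integer(doc_freq[tab$token])
  n_prune <- if (prune_fraction > 0) ceiling(prune_fraction * nrow(tab)) else 0L
  if (n_prune > 0) {
    ord <- order(tab$freq, tab$token)  # ascending frequency, ties lexicographic
    tab <- tab[-ord[seq_len(n_prune)], ]
  }
  ord <- order(-tab$freq, tab$token)
  tab <- tab[ord, ]
  tab$index <- seq_len(nrow(tab)) + 1L
  out <- tab[, c("token", "index", "freq", "doc_freq")]
  class(out) <- c("cvd_vocab", class(out))
  out
}

#' Checksum of a vocabulary (leakage guard)
#'
#' Hash of the token-to-index map; unchanged by encoding any corpus with it.
#'
#' @param vocab a [build_vocabulary()] result.
#' @return Character scalar.
#' @export
vocab_checksum <- function(vocab) {
  rlang::hash(list(vocab$token, vocab$index))
}

#' Default maximum sequence length: 99th percentile of training lengths
#'
#' @param corpus_tokens list of token vectors (training split).
#' @return Integer.
#' @export
default_max_len <- function(corpus_tokens) {
  max(1L, as.integer(ceiling(quantile(lengths(corpus_tokens), 0.99, names = FALSE))))
}

#' Encode token sequences as padded integer matrices
#'
#' Tokens absent from the vocabulary map to the out-of-vocabulary index 1;
#' sequences are right-padded with 0 and truncated to `max_len`. A visit is
#' flagged as not retained when its post-cleaning length (before truncation)
#' is below `min_tokens` (the analysis excludes notes of fewer than 3 words).
#'
#' @param corpus_tokens list of token vectors.
#' @param vocab a [build_vocabulary()] result.
#' @param max_len maximum sequence length (see [default_max_len()]).
#' @param min_tokens minimum post-cleaning length for retention.
#' @return A list of class `cvd_encoded`: `ids` (integer matrix, n x
#'   max_len), `lengths`, `retained` (logical), `max_len`, `vocab_rows`, and
#'   `vocab_hash`.
#' @export
encode_visits <- function(corpus_tokens, vocab, max_len, min_tokens = 3L) {
  stopifnot(max_len >= 1)
  n <- length(corpus_tokens)
  full_len <- lengths(corpus_tokens)
  idx_map <- setNames(vocab$index, vocab$token)
  ids <- matrix(0L, nrow = n, ncol = max_len)
  for (i in seq_len(n)) {
    tk <- corpus_tokens[[i]]
    if (length(tk) == 0) next
    tk <- tk[seq_len(min(length(tk), max_len))]
    m <- unname(idx_map[tk])
    m[is.na(m)] <- 1L
    ids[i, seq_along(m)] <- m
  }
  structure(list(ids = ids, lengths = pmin(full_len, max_len),
                 retained = full_len >= min_tokens, max_len = as.integer(max_len),
                 vocab_rows = max(vocab$index, 1L) + 1L,
                 vocab_hash = vocab_checksum(vocab)),
            class = "cvd_encoded")
}

#' Subset an encoded dataset by row
#'
#' @param enc a [encode_visits()] result.
#' @param idx integer or logical row index.
#' @return A `cvd_encoded` object with the selected rows.
#' @export
encoded_subset <- function(enc, idx) {
  structure(list(ids = enc$ids[idx, , drop = FALSE], lengths = enc$lengths[idx],
                 retained = enc$retained[idx], max_len = enc$max_len,
                 vocab_rows = enc$vocab_rows, vocab_hash = enc$vocab_hash),
            class = "cvd_encoded")
}

#' Write / read a vocabulary as a two-column TSV
#'
#' @param vocab a [build_vocabulary()] result.
#' @param path file path.
#' @return `write_vocabulary()` returns `path` invisibly; `read_vocabulary()`
#'   a `cvd_vocab` tibble (frequencies included when present in the file).
#' @export
write_vocabulary <- function(vocab, path) {
  readr::write_tsv(vocab, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    token = readr::col_character(), .default = readr::col_integer()),
    progress = FALSE)
  class(out) <- c("cvd_vocab", class(out))
  out
}
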