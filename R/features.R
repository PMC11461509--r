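# Token feature templates for the linear tagger backend: lowercase form,
# word shape (full and run-collapsed), 2-4 character prefixes/suffixes,
# numeric indicators, a PK-lexicon membership flag, and a +/-2 token window
# of neighbour forms and shapes, plus a bias. The count per token is fixed
# (19), which keeps the feature matrix layout regular and fast to index.
.N_FEATS <- 19L

word_shape <- function(x) {
  x <- gsub("[A-Z]", "X", x)
  x <- gsub("[a-z]", "x", x)
  gsub("[0-9]", "d", x)
}

featurize_tokens <- function(toks, lexicon) {
  T <- length(toks)
  if (T == 0L) return(character())
  lw <- tolower(toks)
  sh <- word_shape(toks)
  ssh <- gsub("(.)\\1+", "\\1", sh)
  nc <- nchar(lw)
  wm1 <- c("<s>", lw[-T])
  wm2 <- c("<s>", "<s>", if (T > 2L) lw[seq_len(T - 2L)])[seq_len(T)]
  wp1 <- c(lw[-1L], "</s>")
  wp2 <- c(if (T > 2L) lw[seq.int(3L, T)], "</s>", "</s>")[seq_len(T)]
  shm1 <- c("<s>", sh[-T])
  shp1 <- c(sh[-1L], "</s>")
  m <- rbind(
    paste0("w=", lw),
    paste0("sh=", sh),
    paste0("ssh=", ssh),
    paste0("p2=", substr(lw, 1L, 2L)),
    paste0("p3=", substr(lw, 1L, 3L)),
    paste0("p4=", substr(lw, 1L, 4L)),
    paste0("s2=", substring(lw, pmax(1L, nc - 1L))),
    paste0("s3=", substring(lw, pmax(1L, nc - 2L))),
    paste0("s4=", substring(lw, pmax(1L, nc - 3L))),
    paste0("num=", grepl("^[0-9]+([./-][0-9]+)*$", toks) + 0L),
    paste0("dig=", grepl("[0-9]", toks) + 0L),
    paste0("lex=", (lw %in% lexicon) + 0L),
    paste0("w-1=", wm1),
    paste0("w-2=", wm2),
    paste0("w+1=", wp1),
    paste0("w+2=", wp2),
    paste0("sh-1=", shm1),
    paste0("sh+1=", shp1),
    rep("bias", T)
  )
  as.vector(m)  # column-major => token-major blocks of .N_FEATS
}

# Tokenise + featurise every sentence of a corpus once. Returns parallel
# lists: token tables, flat feature strings (token-major), CSR-style token
# pointers, and gold BIO tags.
featurize_corpus <- function(corpus, lexicon, policy = "snap") {
  n <- length(corpus)
  tokens <- vector("list", n); flat <- vector("list", n)
  ptr <- vector("list", n); tags <- vector("list", n)
  for (i in seq_len(n)) {
    s <- corpus$sentences[[i]]
    tk <- pk_tokenize(s$text)
    tokens[[i]] <- tk
    flat[[i]] <- featurize_tokens(tk$text, lexicon)
    ptr[[i]] <- .N_FEATS * (0:nrow(tk))
    tags[[i]] <- spans_to_bio(tk, s$spans, policy = policy)
  }
  list(tokens = tokens, flat = flat, ptr = ptr, tags = tags,
       ids = corpus_ids(corpus))
}

# Map flat feature strings to 1-based vocabulary indices (0 = unseen).
features_to_ids <- function(flat, vocab) {
  lapply(flat, function(f) {
    ix <- match(f, vocab)
    ix[is.na(ix)] <- 0L
    as.integer(ix)
  })
}
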