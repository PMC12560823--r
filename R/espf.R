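## Frequency-based substructure vocabulary (byte-pair-encoding over
## atom-level SMILES units) and tokenization with atom-index alignment.
##
## Base units: one unit per atom token of the canonical SMILES; bond
## symbols, ring-closure digits and branch parentheses are attached to the
## preceding atom's unit for character bookkeeping but contribute no atoms.
## Merging adjacent units therefore yields contiguous SMILES fragments whose
## atom sets partition the molecule — the alignment key every other module
## consumes.

vocabFingerprint <- function(baseTokens, merges, specialIds) {
  sprintf("%08x", fnv1a32(c(baseTokens,
                            apply(merges, 1L, paste, collapse = "\t"),
                            paste(names(specialIds), specialIds))))
}

unitSequence <- function(smiles) parseSmiles(smiles)$units

## Count adjacent unit pairs across all sequences (corpus-order free).
pairCounts <- function(seqs) {
  lefts <- rights <- character(0)
  for (s in seqs) {
    if (length(s) < 2L) next
    lefts <- c(lefts, s[-length(s)])
    rights <- c(rights, s[-1L])
  }
  if (!length(lefts)) return(NULL)
  key <- paste(lefts, rights, sep = "\x1f")
  tab <- table(key)
  data.frame(left = sub("\x1f.*$", "", names(tab)),
             right = sub("^.*\x1f", "", names(tab)),
             freq = as.integer(tab), stringsAsFactors = FALSE)
}

## Left-to-right replacement of one adjacent pair by its merge.
applyMergeToSeq <- function(tokens, sets, left, right, merged) {
  i <- 1L
  while (i < length(tokens)) {
    if (tokens[i] == left && tokens[i + 1L] == right) {
      tokens <- c(head(tokens, i - 1L), merged,
                  if (i + 1L < length(tokens)) tokens[(i + 2L):length(tokens)])
      sets <- c(head(sets, i - 1L), list(c(sets[[i]], sets[[i + 1L]])),
                if (i + 1L < length(sets)) sets[(i + 2L):length(sets)])
    }
    i <- i + 1L
  }
  list(tokens = tokens, sets = sets)
}

#' Learn a substructure vocabulary from a SMILES corpus
#'
#' Starts from atom-level base units and repeatedly merges the most frequent
#' adjacent unit pair whose corpus frequency is at least
#' \code{minFrequency}, until no pair qualifies or the vocabulary reaches
#' \code{maxSize} entries. Ties are broken by frequency and then by the
#' byte-order-smaller merged string, so the result does not depend on corpus
#' order.
#'
#' @param corpus character vector of SMILES strings (canonicalized
#'   internally).
#' @param minFrequency minimum corpus frequency for a merge (default 2).
#' @param maxSize maximum vocabulary size including special ids
#'   (default 2048).
#' @return a \linkS4class{SubstructureVocab}. Ids 1..3 are the mask, pad and
#'   unknown specials; substructure ids follow, dense.
#' @export
buildVocab <- function(corpus, minFrequency = 2L, maxSize = 2048L) {
  if (!length(corpus)) stopf("vocabulary corpus is empty")
  stopifnot(minFrequency >= 1L, maxSize >= 4L)
  cans <- canonicalSmiles(corpus)
  if (all(is.na(cans))) stopf("no valid SMILES in corpus")
  seqs <- lapply(cans[!is.na(cans)], unitSequence)
  base <- sort(unique(unlist(seqs)), method = "radix")
  merges <- data.frame(rank = integer(0), left = character(0),
                       right = character(0), merged = character(0),
                       frequency = integer(0), stringsAsFactors = FALSE)
  nTokens <- 3L + length(base)
  while (nTokens < maxSize) {
    pc <- pairCounts(seqs)
    if (is.null(pc)) break
    pc <- pc[pc$freq >= minFrequency, , drop = FALSE]
    if (!nrow(pc)) break
    pc$merged <- paste0(pc$left, pc$right)
    ord <- order(-pc$freq, pc$merged, method = "radix")
    top <- pc[ord[1L], ]
    merges <- rbind(merges, data.frame(
      rank = nrow(merges) + 1L, left = top$left, right = top$right,
      merged = top$merged, frequency = top$freq, stringsAsFactors = FALSE))
    seqs <- lapply(seqs, function(s) {
      applyMergeToSeq(s, as.list(seq_along(s)), top$left, top$right,
                      top$merged)$tokens
    })
    nTokens <- nTokens + 1L
  }
  tokens <- c(base, merges$merged)
  tokenToId <- seq_along(tokens) + 3L
  names(tokenToId) <- tokens
  specials <- c(mask = 1L, pad = 2L, unknown = 3L)
  new("SubstructureVocab", baseTokens = base, merges = merges,
      tokenToId = tokenToId, specialIds = specials,
      fingerprint = vocabFingerprint(base, merges, specials))
}

#' Tokenize a SMILES into substructure fragments with atom alignment
#'
#' Applies the learned merges in order to the molecule's atom-level unit
#' sequence. Each fragment's atom set is the union of the atoms its units
#' cover; base units never seen in the training corpus map to the unknown id
#' with singleton atom sets. The returned atom sets are pairwise disjoint and
#' cover all heavy atoms.
#'
#' @param smiles a valid SMILES string (canonicalized internally) — the
#'   canonical form is idempotent, so records built by this package
#'   tokenize in their stored atom order.
#' @param vocab a \linkS4class{SubstructureVocab}.
#' @return a \linkS4class{TokenizedMolecule}.
#' @export
tokenizeSmiles <- function(smiles, vocab) {
  can <- canonicalSmiles(smiles)
  if (is.na(can)) stopf("invalid SMILES: %s", smiles)
  units <- unitSequence(can)
  tokens <- units
  sets <- as.list(seq_along(units))
  mg <- vocab@merges
  for (r in seq_len(nrow(mg))) {
    res <- applyMergeToSeq(tokens, sets, mg$left[r], mg$right[r],
                           mg$merged[r])
    tokens <- res$tokens; sets <- res$sets
  }
  ids <- unname(vocab@tokenToId[tokens])
  ids[is.na(ids)] <- vocab@specialIds[["unknown"]]
  new("TokenizedMolecule", fragments = tokens, tokenIds = as.integer(ids),
      atomSets = sets, nAtoms = length(units))
}

#' Atoms covered by a set of substructures
#'
#' @param tok a \linkS4class{TokenizedMolecule}.
#' @param indices integer substructure indices in 1..e (may be empty).
#' @return sorted integer vector of atom indices.
#' @export
atomsOfSubstructures <- function(tok, indices) {
  e <- length(fragments(tok))
  if (length(indices) && any(indices < 1L | indices > e))
    stopf("substructure index out of range 1..%d", e)
  out <- unlist(atomSets(tok)[indices])
  if (is.null(out)) return(integer(0))
  as.integer(sort(unique(out)))
}

#' Vocabulary size (specials + substructure tokens)
#' @param vocab a \linkS4class{SubstructureVocab}.
#' @export
vocabSize <- function(vocab) length(vocab@tokenToId) + length(vocab@specialIds)

#' Write / read a substructure vocabulary as TSV
#'
#' The file stores header lines with the base tokens, special ids and the
#' content fingerprint, followed by one row per merge
#' (rank, left, right, merged, frequency). Reload is bit-exact.
#'
#' @param vocab a \linkS4class{SubstructureVocab}.
#' @param path file path.
#' @export
writeVocab <- function(vocab, path) {
  hdr <- c(paste0("#base\t", paste(vocab@baseTokens, collapse = "\t")),
           paste0("#specials\t",
                  paste(names(vocab@specialIds), vocab@specialIds,
                        sep = "=", collapse = "\t")),
           paste0("#fingerprint\t", vocab@fingerprint),
           "rank\tleft\tright\tmerged\tfrequency")
  rows <- if (nrow(vocab@merges))
    apply(vocab@merges, 1L, function(r)
      paste(trimws(r), collapse = "\t")) else character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname writeVocab
#' @export
readVocab <- function(path) {
  lines <- readLines(path)
  base <- strsplit(sub("^#base\t?", "", lines[1L]), "\t")[[1L]]
  if (identical(base, "") || identical(base, character(0)))
    base <- character(0)
  sp <- strsplit(sub("^#specials\t", "", lines[2L]), "\t")[[1L]]
  specials <- vapply(strsplit(sp, "="), function(x) as.integer(x[2L]),
                     integer(1))
  names(specials) <- vapply(strsplit(sp, "="), `[`, character(1), 1L)
  fp <- sub("^#fingerprint\t", "", lines[3L])
  body <- lines[-(1:4)]
  merges <- if (length(body)) {
    parts <- strsplit(body, "\t")
    data.frame(rank = as.integer(vapply(parts, `[`, "", 1L)),
               left = vapply(parts, `[`, "", 2L),
               right = vapply(parts, `[`, "", 3L),
               merged = vapply(parts, `[`, "", 4L),
               frequency = as.integer(vapply(parts, `[`, "", 5L)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(rank = integer(0), left = character(0), right = character(0),
               merged = character(0), frequency = integer(0),
               stringsAsFactors = FALSE)
  }
  tokens <- c(base, merges$merged)
  tokenToId <- seq_along(tokens) + 3L
  names(tokenToId) <- tokens
  new("SubstructureVocab", baseTokens = base, merges = merges,
      tokenToId = tokenToId, specialIds = specials, fingerprint = fp)
}
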