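## SMILES scanning and molecular graph construction.
##
## The scanner is written here (rather than delegated to OpenBabel) because
## downstream modules need the character->atom alignment: every atom token's
## position in the SMILES string defines an atom-level "unit", and the
## substructure vocabulary merges those units into fragments whose atom-index
## sets are the alignment key shared by the 1D/2D/3D views. No installed
## package exposes that map. Canonicalization and validity checks are
## delegated to OpenBabel via ChemmineOB.

ORGANIC_SINGLE <- c("B", "C", "N", "O", "P", "S", "F", "I")
AROMATIC_SINGLE <- c("b", "c", "n", "o", "p", "s")
ELEMENT_PALETTE <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "other")

#' Canonicalize a SMILES string
#'
#' Converts a SMILES to its OpenBabel canonical form. Invalid SMILES yield
#' \code{NA_character_} rather than an error, so callers can report bad rows.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, \code{NA} where invalid.
#' @export
canonicalSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", source = s),
      error = function(e) "")
    out <- trimws(out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

## Scan a SMILES string into atoms, bonds and per-atom character units.
## Returns list(atoms = data.frame(symbol, aromatic, charge, token, start),
##              bonds = data.frame(a1, a2, order, aromatic),
##              units = character vector, one per atom, concatenating to the
##                      input string).
parseSmiles <- function(smiles) {
  s <- smiles
  nC <- nchar(s)
  if (nC == 0L) stopf("empty SMILES string")
  sym <- character(0); arom <- logical(0); chg <- integer(0)
  tok <- character(0); starts <- integer(0)
  b1 <- integer(0); b2 <- integer(0); bord <- numeric(0); barom <- logical(0)
  prev <- NA_integer_
  stack <- integer(0)
  pending <- NA_real_          # pending explicit bond order
  ring <- list()               # digit -> c(atom, order or NA)

  addBond <- function(a, b, ord) {
    bothArom <- arom[a] && arom[b]
    if (is.na(ord)) ord <- if (bothArom) 1.5 else 1
    b1 <<- c(b1, a); b2 <<- c(b2, b)
    bord <<- c(bord, ord); barom <<- c(barom, ord == 1.5)
  }

  i <- 1L
  while (i <= nC) {
    ch <- substr(s, i, i)
    consumed <- 1L
    atomToken <- NULL; atomSym <- NULL; atomArom <- FALSE; atomChg <- 0L
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, nC), fixed = TRUE)
      if (j < 0) stopf("unclosed bracket atom in SMILES '%s'", s)
      atomToken <- substr(s, i, i + j - 1L)
      inner <- substr(atomToken, 2L, nchar(atomToken) - 1L)
      body <- sub("^[0-9]*", "", inner)                 # strip isotope
      m <- regmatches(body, regexpr("^([A-Z][a-z]?|[a-z]{1,2}|\\*)", body))
      if (!length(m)) stopf("cannot parse bracket atom '%s'", atomToken)
      atomSym <- m
      atomArom <- atomSym == tolower(atomSym) && atomSym != "*"
      if (atomArom) atomSym <- paste0(toupper(substr(atomSym, 1, 1)),
                                      substr(atomSym, 2, nchar(atomSym)))
      plus <- lengths(regmatches(body, gregexpr("\\+", body)))
      minus <- lengths(regmatches(body, gregexpr("-", body)))
      dig <- regmatches(body, regexpr("[+-][0-9]+", body))
      if (length(dig) && nzchar(dig)) {
        atomChg <- as.integer(substr(dig, 2, nchar(dig))) *
          (if (substr(dig, 1, 1) == "+") 1L else -1L)
      } else atomChg <- as.integer(plus - minus)
      consumed <- nchar(atomToken)
    } else if (i < nC && substr(s, i, i + 1L) %in% c("Cl", "Br")) {
      atomToken <- substr(s, i, i + 1L); atomSym <- atomToken
      consumed <- 2L
    } else if (ch %in% ORGANIC_SINGLE) {
      atomToken <- ch; atomSym <- ch
    } else if (ch %in% AROMATIC_SINGLE) {
      atomToken <- ch; atomSym <- toupper(ch); atomArom <- TRUE
    } else if (ch == "(") {
      stack <- c(stack, prev)
    } else if (ch == ")") {
      if (!length(stack)) stopf("unbalanced ')' in SMILES '%s'", s)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
    } else if (ch == "-") { pending <- 1
    } else if (ch == "=") { pending <- 2
    } else if (ch == "#") { pending <- 3
    } else if (ch == ":") { pending <- 1.5
    } else if (ch %in% c("/", "\\")) { pending <- 1   # stereo bonds: single
    } else if (ch == "@") { # stray chirality outside brackets: ignore
    } else if (ch == "%" || grepl("^[0-9]$", ch)) {
      if (ch == "%") {
        d <- substr(s, i + 1L, i + 2L); consumed <- 3L
      } else d <- ch
      if (is.na(prev)) stopf("ring closure before any atom in '%s'", s)
      if (!is.null(ring[[d]])) {
        op <- ring[[d]]
        ord <- if (!is.na(op$order)) op$order else pending
        addBond(op$atom, prev, ord)
        ring[[d]] <- NULL
      } else {
        ring[[d]] <- list(atom = prev, order = pending)
      }
      pending <- NA_real_
    } else if (ch == ".") {
      stopf("multi-component (dot-separated) SMILES are not supported: '%s'", s)
    } else {
      stopf("unsupported SMILES character '%s' in '%s'", ch, s)
    }
    if (!is.null(atomToken)) {
      sym <- c(sym, atomSym); arom <- c(arom, atomArom); chg <- c(chg, atomChg)
      tok <- c(tok, atomToken); starts <- c(starts, i)
      k <- length(sym)
      if (!is.na(prev)) { addBond(prev, k, pending); pending <- NA_real_ }
      prev <- k
    }
    i <- i + consumed
  }
  if (length(ring)) stopf("unclosed ring bond in SMILES '%s'", s)
  if (!length(sym)) stopf("SMILES '%s' contains no atoms", s)
  n <- length(sym)
  ends <- c(starts[-1L] - 1L, nC)
  units <- substring(s, starts, ends)
  if (starts[1L] > 1L)  # leading bond/branch chars attach to the first unit
    units[1L] <- paste0(substr(s, 1L, starts[1L] - 1L), units[1L])
  list(
    atoms = data.frame(symbol = sym, aromatic = arom, charge = chg,
                       token = tok, start = starts,
                       stringsAsFactors = FALSE),
    bonds = data.frame(a1 = b1, a2 = b2, order = bord, aromatic = barom),
    units = units)
}

## Which bonds lie on a ring: a bond is in a ring iff it is not a bridge.
## Molecules are tiny, so remove-and-check connectivity is adequate.
ringBondFlags <- function(n, bonds) {
  m <- nrow(bonds)
  if (m == 0L) return(logical(0))
  adj <- function(drop) {
    a <- vector("list", n)
    for (e in seq_len(m)) {
      if (e == drop) next
      a[[bonds$a1[e]]] <- c(a[[bonds$a1[e]]], bonds$a2[e])
      a[[bonds$a2[e]]] <- c(a[[bonds$a2[e]]], bonds$a1[e])
    }
    a
  }
  connected <- function(a, from, to) {
    seen <- logical(n); queue <- from; seen[from] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (v == to) return(TRUE)
      nb <- a[[v]][!seen[a[[v]]]]
      seen[nb] <- TRUE; queue <- c(queue, nb)
    }
    FALSE
  }
  vapply(seq_len(m), function(e)
    connected(adj(e), bonds$a1[e], bonds$a2[e]), logical(1))
}

## Node feature layout (columns):
##   1..10 element one-hot (ELEMENT_PALETTE), 11 degree/4, 12 formal charge,
##   13 aromatic flag, 14..16 hybridization one-hot (sp, sp2, sp3),
##   17 mask flag (set only by the 2D perturbation).
## Edge features: order/3, conjugated (aromatic) flag, ring flag.
NODE_FEATURE_DIM <- 17L
EDGE_FEATURE_DIM <- 3L

nodeFeatureMatrix <- function(parsed) {
  at <- parsed$atoms; bd <- parsed$bonds
  n <- nrow(at)
  deg <- tabulate(c(bd$a1, bd$a2), nbins = n)
  hasTriple <- hasDouble <- logical(n)
  for (e in seq_len(nrow(bd))) {
    if (bd$order[e] == 3) hasTriple[c(bd$a1[e], bd$a2[e])] <- TRUE
    if (bd$order[e] == 2) hasDouble[c(bd$a1[e], bd$a2[e])] <- TRUE
  }
  hyb <- ifelse(hasTriple, 1L, ifelse(at$aromatic | hasDouble, 2L, 3L))
  f <- matrix(0, n, NODE_FEATURE_DIM)
  ei <- match(at$symbol, ELEMENT_PALETTE)
  ei[is.na(ei)] <- length(ELEMENT_PALETTE)
  f[cbind(seq_len(n), ei)] <- 1
  f[, 11L] <- deg / 4
  f[, 12L] <- at$charge
  f[, 13L] <- as.numeric(at$aromatic)
  f[cbind(seq_len(n), 13L + hyb)] <- 1
  f
}

edgeFeatureMatrix <- function(parsed) {
  bd <- parsed$bonds
  ringf <- ringBondFlags(nrow(parsed$atoms), bd)
  cbind(order = bd$order / 3,
        conjugated = as.numeric(bd$aromatic),
        ring = as.numeric(ringf))
}

## DFS SMILES writer for an induced subgraph. Returns list(smiles, order)
## where order maps output atom position -> original atom index. Candidate
## neighbours are visited in ascending index order, making the writer
## deterministic and giving round trips the identity atom mapping.
writeSmilesGraph <- function(parsed, keep = seq_len(nrow(parsed$atoms))) {
  at <- parsed$atoms; bd <- parsed$bonds
  keep <- sort(keep)
  sub <- bd[bd$a1 %in% keep & bd$a2 %in% keep, , drop = FALSE]
  adj <- lapply(seq_len(nrow(at)), function(i) integer(0))
  bondOf <- new.env()
  for (e in seq_len(nrow(sub))) {
    a <- sub$a1[e]; b <- sub$a2[e]
    adj[[a]] <- sort(c(adj[[a]], b)); adj[[b]] <- sort(c(adj[[b]], a))
    assign(paste(min(a, b), max(a, b)), sub[e, ], envir = bondOf)
  }
  bondSym <- function(a, b) {
    info <- get(paste(min(a, b), max(a, b)), envir = bondOf)
    both <- at$aromatic[a] && at$aromatic[b]
    if (info$order == 2) "=" else if (info$order == 3) "#"
    else if (info$order == 1.5) (if (both) "" else ":")
    else if (both) "-" else ""
  }
  atomTok <- function(i) {
    if (startsWith(at$token[i], "[")) return(at$token[i])
    if (at$aromatic[i]) tolower(at$symbol[i]) else at$symbol[i]
  }
  ## pass 1: DFS spanning forest; classify tree vs ring-closure edges
  visited <- logical(nrow(at))
  children <- lapply(seq_len(nrow(at)), function(i) integer(0))
  backAt <- lapply(seq_len(nrow(at)), function(i) character(0))
  ringLab <- list(); ringNum <- 0L
  order <- integer(0)
  roots <- integer(0)
  dfs1 <- function(i, from) {
    visited[i] <<- TRUE
    order <<- c(order, i)
    for (b in adj[[i]]) {
      if (!is.na(from) && b == from) next
      key <- paste(min(i, b), max(i, b))
      if (visited[b]) {
        if (is.null(ringLab[[key]])) {
          ringNum <<- ringNum + 1L
          ringLab[[key]] <<- if (ringNum < 10L) as.character(ringNum)
                             else paste0("%", sprintf("%02d", ringNum))
          backAt[[i]] <<- c(backAt[[i]], key)
          backAt[[b]] <<- c(backAt[[b]], key)
        }
      } else {
        children[[i]] <<- c(children[[i]], b)
        dfs1(b, i)
      }
    }
  }
  for (root in keep) if (!visited[root]) { roots <- c(roots, root); dfs1(root, NA_integer_) }
  ## pass 2: emit tokens, ring digits at both endpoints, branches wrapped
  emit <- function(i, from) {
    out <- atomTok(i)
    for (key in backAt[[i]]) {
      ends <- as.integer(strsplit(key, " ")[[1L]])
      other <- if (ends[1L] == i) ends[2L] else ends[1L]
      sym <- bondSym(i, other)
      out <- paste0(out, sym, ringLab[[key]])
    }
    kids <- children[[i]]
    for (k in seq_along(kids)) {
      b <- kids[k]
      branch <- paste0(bondSym(i, b), emit(b, i))
      out <- paste0(out,
                    if (k < length(kids)) paste0("(", branch, ")") else branch)
    }
    out
  }
  pieces <- vapply(roots, function(r) emit(r, NA_integer_), character(1))
  list(smiles = paste(pieces, collapse = "."), order = order)
}

#' Bemis-Murcko scaffold key of a molecule
#'
#' Computes the ring-system-plus-linker framework by iteratively pruning
#' terminal (degree-1) atoms; the remaining subgraph is written as SMILES and
#' canonicalized to obtain a split key. Acyclic molecules have an empty
#' framework and are keyed by their own canonical SMILES, so that every
#' molecule belongs to a well-defined scaffold group.
#'
#' @param smiles a single canonical SMILES string.
#' @return a scaffold key string.
#' @export
murckoScaffold <- function(smiles) {
  parsed <- parseSmiles(smiles)
  n <- nrow(parsed$atoms)
  keep <- rep(TRUE, n)
  bd <- parsed$bonds
  repeat {
    deg <- tabulate(c(bd$a1[keep[bd$a1] & keep[bd$a2]],
                      bd$a2[keep[bd$a1] & keep[bd$a2]]), nbins = n)
    drop <- keep & deg <= 1L
    if (!any(drop & keep)) break
    changed <- keep & drop
    if (!any(changed)) break
    keep[changed] <- FALSE
    if (!any(keep)) break
  }
  if (!any(keep)) return(canonicalSmiles(smiles))
  raw <- writeSmilesGraph(parsed, which(keep))$smiles
  can <- canonicalSmiles(raw)
  if (is.na(can)) raw else can
}

## Deterministic VF2-style mapping from one small graph onto an isomorphic
## one (used to express SDF-ordered coordinates in canonical-SMILES atom
## order). Candidates are tried in ascending index order so that identical
## orderings yield the identity map. Returns an integer vector map with
## map[i] = index in graph B matching atom i of graph A, or NULL.
matchAtoms <- function(symA, bondsA, symB, bondsB) {
  n <- length(symA)
  if (n != length(symB) || nrow(bondsA) != nrow(bondsB)) return(NULL)
  adjA <- lapply(seq_len(n), function(i) integer(0))
  adjB <- lapply(seq_len(n), function(i) integer(0))
  for (e in seq_len(nrow(bondsA))) {
    adjA[[bondsA$a1[e]]] <- c(adjA[[bondsA$a1[e]]], bondsA$a2[e])
    adjA[[bondsA$a2[e]]] <- c(adjA[[bondsA$a2[e]]], bondsA$a1[e])
  }
  for (e in seq_len(nrow(bondsB))) {
    adjB[[bondsB$a1[e]]] <- c(adjB[[bondsB$a1[e]]], bondsB$a2[e])
    adjB[[bondsB$a2[e]]] <- c(adjB[[bondsB$a2[e]]], bondsB$a1[e])
  }
  degA <- lengths(adjA); degB <- lengths(adjB)
  map <- rep(NA_integer_, n); used <- logical(n)
  search <- function(i) {
    if (i > n) return(TRUE)
    for (j in seq_len(n)) {
      if (used[j] || symB[j] != symA[i] || degB[j] != degA[i]) next
      ## consistency with already-mapped neighbours
      ok <- TRUE
      for (nb in adjA[[i]]) {
        if (nb < i && !(map[nb] %in% adjB[[j]])) { ok <- FALSE; break }
      }
      if (!ok) next
      ## mapped B-neighbours of j must correspond to A-neighbours of i
      for (nbB in adjB[[j]]) {
        k <- match(nbB, map)
        if (!is.na(k) && !(k %in% adjA[[i]])) { ok <- FALSE; break }
      }
      if (!ok) next
      map[i] <<- j; used[j] <<- TRUE
      if (search(i + 1L)) return(TRUE)
      map[i] <<- NA_integer_; used[j] <<- FALSE
    }
    FALSE
  }
  if (search(1L)) map else NULL
}
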