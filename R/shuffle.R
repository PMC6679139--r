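# Exact dinucleotide-preserving shuffle (Altschul-Erickson style).
#
# A shuffled sequence must realize exactly the same multiset of adjacent
# base pairs as the input. Treating bases as vertices and dinucleotides as
# directed edges, any such sequence is an Eulerian path through the same
# multigraph, so it necessarily starts and ends on the original first and
# last bases. We sample uniformly by drawing a random "last-edge" arborescence
# toward the terminal vertex (rejection sampling), permuting the remaining
# out-edges of each vertex, and walking the path.

#' Dinucleotide-preserving shuffle of a DNA sequence
#'
#' Produces a random permutation of `seq` with exactly the same 16-entry
#' dinucleotide count vector (and hence the same first and last base). Used
#' to build matched negative sequences for TFBS positives: the shuffle keeps
#' local composition while destroying any positional motif.
#'
#' @param seq A DNA string over A, C, G, T with at least 2 characters.
#'   Sequences containing N are rejected; filter those out first.
#' @param seed Optional integer seed making the shuffle deterministic. The
#'   caller's RNG state is left untouched when a seed is given.
#' @return A shuffled DNA string of the same length.
#' @examples
#' s <- dinucleotide_shuffle("ACGTACGTAC", seed = 1)
#' nchar(s) == 10
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) stop("dinucleotide_shuffle() needs a sequence of length >= 2")
  if (any(chars == "N")) {
    stop("sequence contains N; filter N-containing sequences before shuffling")
  }
  code <- match(chars, c("A", "C", "G", "T"))
  if (anyNA(code)) stop("sequence contains characters outside {A,C,G,T}")

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }

  first <- code[[1L]]
  last <- code[[n]]

  # out-edge multisets: succ[[v]] = successors of vertex v in input order
  succ <- split(code[-1L], code[-n])
  verts <- as.integer(names(succ))
  succ_full <- vector("list", 4L)
  succ_full[verts] <- succ

  # vertices with out-edges, excluding the terminal vertex, need a last edge
  need_last <- verts[verts != last]

  repeat {
    last_edge <- vapply(need_last, function(v) {
      s <- succ_full[[v]]
      s[[sample.int(length(s), 1L)]]
    }, integer(1L))
    names(last_edge) <- need_last
    # every vertex with out-edges must reach `last` by following last edges
    ok <- TRUE
    for (v in need_last) {
      cur <- v
      seen <- integer(0)
      while (cur != last) {
        if (cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
        nxt <- last_edge[as.character(cur)]
        if (is.na(nxt)) { ok <- FALSE; break }  # dead end before terminal
        cur <- as.integer(nxt)
      }
      if (!ok) break
    }
    if (ok) break
  }

  # permute remaining edges, append the reserved last edge
  for (v in verts) {
    s <- succ_full[[v]]
    if (v != last) {
      le <- last_edge[[as.character(v)]]
      pos <- match(le, s)
      s <- s[-pos]
      if (length(s) > 1L) s <- s[sample.int(length(s))]
      s <- c(s, le)
    } else {
      if (length(s) > 1L) s <- s[sample.int(length(s))]
    }
    succ_full[[v]] <- s
  }

  # walk the Eulerian path from the original start vertex
  out <- integer(n)
  out[[1L]] <- first
  ptr <- integer(4L)  # per-vertex consumption pointer
  cur <- first
  for (i in 2L:n) {
    ptr[cur] <- ptr[cur] + 1L
    nxt <- succ_full[[cur]][[ptr[cur]]]
    out[[i]] <- nxt
    cur <- nxt
  }
  paste(c("A", "C", "G", "T")[out], collapse = "")
}

#' Dinucleotide count vector of a DNA string
#'
#' Counts all 16 adjacent base pairs; used by tests and callers to verify the
#' shuffle contract.
#'
#' @param seq A DNA string over A, C, G, T.
#' @return A named integer vector of length 16 (AA, AC, ..., TT).
#' @export
dinucleotide_counts <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  keys <- as.vector(outer(bases, bases, paste0))  # AA, CA, GA, TA, AC, ...
  keys <- sort(keys)
  n <- length(chars)
  out <- stats::setNames(integer(16L), keys)
  if (n >= 2L) {
    di <- paste0(chars[-n], chars[-1L])
    tab <- table(di)
    out[names(tab)] <- as.integer(tab)
  }
  out
}
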