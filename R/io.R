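#' Read unaligned protein sequences from a FASTA file
#'
#' Sequences are uppercased and stripped of gap characters (`-`, `.`).  Only
#' the 20 standard amino acids plus the tolerated ambiguity codes
#' (X, B, Z, U, O) may remain after sanitization.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of residue strings, in file order, with
#'   sequence identifiers as names.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate identifier ", dup[[1L]])
  seqs <- toupper(as.character(set))
  seqs <- gsub("[-.*]", "", seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence after sanitization: ", ids[!nzchar(seqs)][1L])
  }
  bad <- grepl(paste0("[^", paste(c(AA, names(AMBIGUITY)), collapse = ""), "]"), seqs)
  if (any(bad)) stop("unrecognized residue code in sequence ", ids[bad][1L])
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param records Named character vector of residue strings.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a multiple sequence alignment to an aligned FASTA file
#'
#' @param msa Named character vector of aligned rows (equal lengths, `-` for
#'   gaps).
#' @param path Output path.
#' @export
write_msa <- function(msa, path) {
  if (length(unique(nchar(msa))) != 1L) stop("ragged alignment rows")
  write_fasta(msa, path)
}

#' Read a guide tree in Newick format
#'
#' The tree is returned rooted.  An unrooted, trifurcating input tree is
#' converted deterministically to a rooted binary tree by splitting the
#' longest pendant edge at the basal trifurcation.  Negative branch lengths
#' are clamped to zero with a warning.
#'
#' @param path Path to a Newick file.
#' @param taxa Optional character vector of expected leaf labels; an error is
#'   raised if the tree's leaf set differs.
#' @return A rooted binary tree of class `phylo` with branch lengths.
#' @export
read_newick <- function(path, taxa = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  as_guide_tree(tr, taxa = taxa)
}

#' Coerce a phylo object to a rooted binary guide tree
#'
#' @param tr A `phylo` object with branch lengths.
#' @param taxa Optional expected leaf labels.
#' @return A rooted binary `phylo`.
#' @export
as_guide_tree <- function(tr, taxa = NULL) {
  if (is.null(tr$edge.length)) stop("guide tree must have branch lengths")
  if (!is.null(taxa)) {
    missing_ <- setdiff(tr$tip.label, taxa)
    if (length(missing_)) {
      stop("tree leaf '", missing_[[1L]], "' absent from input sequences")
    }
    missing2 <- setdiff(taxa, tr$tip.label)
    if (length(missing2)) {
      stop("sequence '", missing2[[1L]], "' absent from guide tree")
    }
  }
  if (any(tr$edge.length < 0)) {
    warning("negative branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  if (!ape::is.rooted(tr) || !ape::is.binary(tr)) {
    tr <- root_trifurcation(tr)
  }
  tr
}

# Root an unrooted (basal trifurcation) tree by splitting the longest pendant
# edge at the root; deterministic so the progressive order is reproducible.
root_trifurcation <- function(tr) {
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  basal <- which(tr$edge[, 1L] == root)
  if (length(basal) < 3L) {
    # rooted but multifurcating elsewhere: resolve arbitrarily (deterministic)
    tr2 <- ape::multi2di(tr, random = FALSE)
    return(tr2)
  }
  k <- basal[which.max(tr$edge.length[basal])]
  child <- tr$edge[k, 2L]
  target <- if (child <= ntip) tr$tip.label[child] else ape::extract.clade(tr, child)$tip.label
  pos <- tr$edge.length[k] / 2
  tr2 <- phangorn::midpoint(tr)  # fallback if root.phylo fails below
  out <- tryCatch(
    ape::root(tr, outgroup = target, resolve.root = TRUE, edgelabel = FALSE),
    error = function(e) NULL
  )
  if (!is.null(out) && ape::is.binary(out)) {
    # split the pendant edge evenly between the two basal branches
    nb <- which(out$edge[, 1L] == length(out$tip.label) + 1L)
    if (length(nb) == 2L && any(out$edge.length[nb] == 0)) {
      tot <- sum(out$edge.length[nb])
      out$edge.length[nb] <- tot / 2
    }
    return(out)
  }
  tr2
}

#' Write a tree in Newick format
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
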