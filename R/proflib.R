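#' Context profile libraries
#'
#' A context profile library holds `K` profiles, each a `20 x width` matrix of
#' per-offset amino-acid distributions (columns sum to 1, offsets
#' `-(width-1)/2 .. +(width-1)/2`), together with profile priors summing to 1.
#' Leaf sequences are matched against the library to derive position-specific
#' substitution profiles.
#'
#' @param priors Numeric vector of K profile priors.
#' @param profiles List of K matrices, each 20 rows (amino acids in canonical
#'   order) by `width` columns.
#' @return An object of class `context_profile_library`.
#' @export
context_profile_library <- function(priors, profiles) {
  K <- length(profiles)
  stopifnot(K >= 1L, length(priors) == K)
  width <- ncol(profiles[[1L]])
  if (width %% 2L != 1L) stop("profile width must be odd")
  ps <- sum(priors)
  if (abs(ps - 1) > 1e-6) {
    msg("profile priors sum to ", format(ps), "; renormalizing")
  }
  priors <- priors / ps
  for (k in seq_len(K)) {
    p <- profiles[[k]]
    if (nrow(p) != 20L || ncol(p) != width) stop("profile ", k, " has wrong shape")
    cs <- colSums(p)
    if (any(abs(cs - 1) > 0.05)) {
      stop("profile ", k, " has a non-stochastic column (sum ",
           format(cs[which.max(abs(cs - 1))]), ")")
    }
    if (any(abs(cs - 1) > 1e-6)) {
      profiles[[k]] <- sweep(p, 2L, cs, "/")
    }
    rownames(profiles[[k]]) <- AA
  }
  structure(list(K = K, width = width, priors = priors, profiles = profiles),
            class = "context_profile_library")
}

#' @export
print.context_profile_library <- function(x, ...) {
  cat("Context profile library:", x$K, "profiles, width", x$width, "\n")
  invisible(x)
}

#' Read a context profile library
#'
#' Two dialects are supported: `native_tsv`, this package's plain-text format
#' (see Details), and `cs_blast`, a tolerant reader for CS-BLAST-style
#' libraries such as K4000.lib.  Column distributions are renormalized if they
#' are off by more than 1e-6 and rejected if far from stochastic.
#'
#' @details The native TSV format starts with `K`, `width` and `alphabet`
#' header lines, followed by one `profile <k> <prior>` line per profile and
#' `width` rows of 20 tab-separated probabilities (window offsets in order,
#' amino acids in the declared alphabet order).  Lines starting with `#` are
#' comments.
#'
#' The CS-BLAST reader splits the file into profile blocks, reads the prior
#' from a `PRIOR` field, and decodes data rows of 20 fields either as plain
#' probabilities or, when values exceed 1, as scaled negative log2
#' probabilities (`p = 2^(-v/1000)`, `*` meaning probability 0); the chosen
#' interpretation is reported via a message.
#'
#' @param path Path to the library file.
#' @param dialect `"native_tsv"` or `"cs_blast"`.
#' @return A [context_profile_library()].
#' @export
read_profile_library <- function(path, dialect = c("native_tsv", "cs_blast")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "native_tsv") parse_native_tsv(lines) else parse_cs_blast(lines)
}

parse_native_tsv <- function(lines) {
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- function(key) {
    i <- which(vapply(fields, function(f) f[[1L]] == key, logical(1L)))[1L]
    if (is.na(i)) stop("missing header line: ", key)
    fields[[i]]
  }
  K <- as.integer(hdr("K")[2L])
  width <- as.integer(hdr("width")[2L])
  alphabet <- strsplit(hdr("alphabet")[2L], "")[[1L]]
  if (!setequal(alphabet, AA)) stop("alphabet must cover the 20 amino acids")
  perm <- match(AA, alphabet)
  starts <- which(vapply(fields, function(f) f[[1L]] == "profile", logical(1L)))
  if (length(starts) != K) stop("declared K=", K, " but found ", length(starts), " profiles")
  priors <- numeric(K)
  profiles <- vector("list", K)
  for (i in seq_len(K)) {
    priors[i] <- as.numeric(fields[[starts[i]]][3L])
    rows <- fields[(starts[i] + 1L):(starts[i] + width)]
    m <- t(vapply(rows, function(f) as.numeric(f), numeric(20L)))
    if (nrow(m) != width) stop("profile ", i, ": width ", nrow(m), " != declared ", width)
    profiles[[i]] <- t(m)[perm, , drop = FALSE]  # 20 x width, canonical order
  }
  context_profile_library(priors, profiles)
}

parse_cs_blast <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  # profile blocks are delimited by "//" or by ContextProfile records
  idx <- grepl("^(ContextProfile|Profile)\\b", lines) | lines == "//"
  block_id <- cumsum(grepl("^(ContextProfile|Profile)\\b", lines))
  keep <- block_id > 0 & lines != "//"
  blocks <- split(lines[keep], block_id[keep])
  priors <- numeric(0)
  profiles <- list()
  log_decoded <- FALSE
  for (b in blocks) {
    prior_line <- grep("^PRIOR", b, value = TRUE)
    prior <- if (length(prior_line)) as.numeric(strsplit(trimws(prior_line[[1L]]), "\\s+")[[1L]][2L]) else NA_real_
    data_rows <- grep("^\\s*[0-9]+(\\s+[-0-9.*eE+]+){20}\\s*$", b, value = TRUE)
    if (!length(data_rows)) next
    vals <- lapply(strsplit(trimws(data_rows), "\\s+"), function(f) {
      v <- f[-1L][seq_len(20L)]
      out <- suppressWarnings(as.numeric(v))
      out[v == "*"] <- Inf
      out
    })
    m <- do.call(rbind, vals)          # width x 20
    if (max(m[is.finite(m)]) > 1.5) {  # scaled -log2 probabilities
      m <- 2^(-m / 1000)
      m[!is.finite(m)] <- 0
      log_decoded <- TRUE
    } else {
      m[!is.finite(m)] <- 0
    }
    profiles[[length(profiles) + 1L]] <- t(m)
    priors <- c(priors, prior)
  }
  if (!length(profiles)) stop("no profiles found in CS-BLAST library")
  if (log_decoded) {
    msg("cs_blast dialect: decoded data fields as -1000*log2 probabilities")
  } else {
    msg("cs_blast dialect: decoded data fields as plain probabilities")
  }
  if (anyNA(priors)) {
    if (all(is.na(priors))) priors <- rep(1, length(profiles)) else
      priors[is.na(priors)] <- mean(priors, na.rm = TRUE)
  }
  if (all(priors <= 0)) priors <- exp(priors)  # log-space priors
  context_profile_library(priors, profiles)
}

#' Write a context profile library in the native TSV dialect
#'
#' @param lib A [context_profile_library()].
#' @param path Output path.
#' @export
write_profile_library <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# graphmsa context profile library",
               paste0("K\t", lib$K),
               paste0("width\t", lib$width),
               paste0("alphabet\t", paste(AA, collapse = ""))), con)
  for (k in seq_len(lib$K)) {
    writeLines(paste("profile", k, format(lib$priors[k], digits = 17), sep = "\t"), con)
    m <- t(lib$profiles[[k]])  # width x 20
    writeLines(apply(m, 1L, function(r) paste(format(r, digits = 17), collapse = "\t")), con)
  }
  invisible(path)
}

#' Generate a small synthetic context profile library
#'
#' Deterministic per seed.  The library always contains one near-delta profile
#' (each column concentrated on a single amino acid) and one near-uniform
#' profile; remaining profiles have random Dirichlet-like columns.  Intended
#' for tests and examples so that no external library download is required.
#'
#' @param seed Integer seed.
#' @param K Number of profiles (>= 2).
#' @param width Odd window width.
#' @return A [context_profile_library()].
#' @export
generate_test_library <- function(seed = 1L, K = 8L, width = 13L) {
  stopifnot(K >= 2L, width %% 2L == 1L)
  profiles <- with_local_seed(seed, {
    lapply(seq_len(K), function(k) {
      m <- matrix(0, 20L, width)
      if (k == 1L) {            # near-delta
        for (j in seq_len(width)) {
          a <- sample.int(20L, 1L)
          m[, j] <- 0.002
          m[a, j] <- 1 - 0.002 * 19
        }
      } else if (k == 2L) {     # near-uniform
        m[] <- 1 / 20
        m <- m + matrix(runif(20L * width, -1e-4, 1e-4), 20L)
      } else {
        g <- matrix(rgamma(20L * width, shape = 0.5), 20L)
        m <- sweep(g, 2L, colSums(g), "/")
      }
      sweep(m, 2L, colSums(m), "/")
    })
  })
  priors <- rep(1 / K, K)
  context_profile_library(priors, profiles)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
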