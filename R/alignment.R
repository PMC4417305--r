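#' Read a three-way human/chimp/ancestor alignment from MAF
#'
#' Parses a MAF (multiple alignment format) file into blocks of three
#' gapped rows: human, chimpanzee, and their inferred common ancestor,
#' anchored on human coordinates. Species are matched against the `src`
#' field of each `s` line by its prefix before the first `.` (or the
#' whole field when it has no `.`); the part after the `.` names the
#' chromosome. Rows are upper-cased and characters outside `A/C/G/T/-`
#' are mapped to `N`. Blocks missing any of the three species are
#' skipped with a warning and counted in `n_rejected`; rows of unequal
#' length within a block are a parse error. The human row must be on
#' the `+` strand (blocks are human-anchored).
#'
#' @param path Path to a MAF file.
#' @param species Named character vector with entries `human`, `chimp`,
#'   `ancestor` giving the source labels used in the file.
#' @return An object of class `triple_alignment`: a list with `blocks`
#'   (each a list `chrom`, `start`, `human`, `chimp`, `ancestor`) and
#'   `n_rejected`.
#' @export
read_maf <- function(path, species = c(human = "human", chimp = "chimp",
                                       ancestor = "ancestor")) {
  if (!all(c("human", "chimp", "ancestor") %in% names(species)))
    .stopf("species must name human, chimp and ancestor labels")
  lines <- readLines(path)
  blocks <- list()
  n_rejected <- 0L
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (!all(c("human", "chimp", "ancestor") %in% names(cur$rows))) {
      n_rejected <<- n_rejected + 1L
      warning("MAF block missing a species row; skipped", call. = FALSE)
      return(NULL)
    }
    lens <- nchar(vapply(cur$rows, `[[`, character(1), "text"))
    if (length(unique(lens)) != 1L)
      .stopf("MAF block rows have unequal lengths")
    blocks[[length(blocks) + 1L]] <<- list(
      chrom = cur$rows$human$chrom,
      start = cur$rows$human$start,
      human = cur$rows$human$text,
      chimp = cur$rows$chimp$text,
      ancestor = cur$rows$ancestor$text
    )
    NULL
  }
  for (ln in lines) {
    if (grepl("^a( |$)", ln)) {
      flush(cur)
      cur <- list(rows = list())
    } else if (grepl("^s ", ln) && !is.null(cur)) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1L]]
      if (length(f) < 7L) .stopf("malformed s line: '%s'", ln)
      src <- f[2L]
      prefix <- sub("\\..*$", "", src)
      chrom <- if (grepl(".", src, fixed = TRUE)) sub("^[^.]*\\.", "", src) else src
      who <- names(species)[match(prefix, species)]
      if (is.na(who)) next  # unrelated species row; ignore
      text <- toupper(f[7L])
      text <- gsub("[^ACGT-]", "N", text)
      if (who == "human" && f[5L] != "+")
        .stopf("human MAF row must be on the + strand")
      cur$rows[[who]] <- list(chrom = chrom, start = as.integer(f[3L]), text = text)
    }
  }
  flush(cur)
  structure(list(blocks = blocks, n_rejected = n_rejected),
            class = "triple_alignment")
}

#' @export
print.triple_alignment <- function(x, ...) {
  cat(sprintf("triple_alignment: %d block(s), %d rejected\n",
              length(x$blocks), x$n_rejected))
  for (b in utils::head(x$blocks, 5L)) {
    cat(sprintf("  %s:%d width %d\n", b$chrom, b$start, nchar(b$human)))
  }
  if (length(x$blocks) > 5L) cat(sprintf("  ... and %d more\n", length(x$blocks) - 5L))
  invisible(x)
}

#' Construct a triple alignment in memory
#'
#' Builds a `triple_alignment` object directly from gapped row strings,
#' bypassing MAF serialisation. Used by the simulator and convenient in
#' tests.
#'
#' @param blocks A list of lists, each with `chrom`, `start` (0-based
#'   human anchor), `human`, `chimp`, `ancestor` strings of equal length.
#' @return A `triple_alignment` object.
#' @export
triple_alignment <- function(blocks) {
  for (b in blocks) {
    lens <- nchar(c(b$human, b$chimp, b$ancestor))
    if (length(unique(lens)) != 1L) .stopf("block rows have unequal lengths")
  }
  structure(list(blocks = blocks, n_rejected = 0L), class = "triple_alignment")
}

#' Write a triple alignment to MAF
#'
#' @param aln A `triple_alignment` object.
#' @param path Output path.
#' @param species Named character vector of source labels
#'   (see [read_maf()]); chromosome names are appended after a dot.
#' @param src_sizes Optional named vector of chromosome lengths used for
#'   the `srcSize` field; defaults to the ungapped row length.
#' @return `path`, invisibly.
#' @export
write_maf <- function(aln, path, species = c(human = "human", chimp = "chimp",
                                             ancestor = "ancestor"),
                      src_sizes = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  for (b in aln$blocks) {
    writeLines("a", con)
    for (who in c("human", "chimp", "ancestor")) {
      text <- b[[who]]
      ungapped <- nchar(gsub("-", "", text, fixed = TRUE))
      start <- if (who == "human") b$start else 0L
      size <- src_sizes[[b$chrom]] %||% ungapped
      writeLines(sprintf("s %s.%s %d %d + %d %s",
                         species[[who]], b$chrom, start, ungapped, size, text), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

## Precompute per-block arrays used by the counting routines:
## character vectors, human coordinates per column (NA at human gaps),
## and for each species the nearest non-gap neighbour base on each side
## (NA at the block edge).
.prep_block <- function(block) {
  h <- .chars(block$human)
  c_ <- .chars(block$chimp)
  a <- .chars(block$ancestor)
  L <- length(h)
  hpos <- rep(NA_integer_, L)
  ng <- h != "-"
  hpos[ng] <- block$start + seq_len(sum(ng)) - 1L
  neighbour <- function(x) {
    p <- which(x != "-")
    if (length(p) == L) {  # gapless fast path: neighbours are adjacent columns
      return(list(prev = c(NA_character_, x[-L]), nxt = c(x[-1L], NA_character_)))
    }
    prev <- rep(NA_character_, L)
    nxt <- rep(NA_character_, L)
    if (length(p)) {
      i_prev <- findInterval(seq_len(L) - 1L, p)    # last non-gap strictly before i
      prev[i_prev > 0L] <- x[p[i_prev[i_prev > 0L]]]
      i_next <- findInterval(seq_len(L), p) + 1L    # first non-gap strictly after i
      ok <- i_next <= length(p)
      nxt[ok] <- x[p[i_next[ok]]]
    }
    list(prev = prev, nxt = nxt)
  }
  ng_cols <- which(ng)
  list(h = h, c = c_, a = a, L = L, hpos = hpos,
       ng_cols = ng_cols, ng_pos = hpos[ng_cols],
       nb = list(human = neighbour(h), chimp = neighbour(c_), ancestor = neighbour(a)))
}
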