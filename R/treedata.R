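#' Area alphabet
#'
#' An ordered set of single-letter geographic area codes (at most ten).  The
#' order is fixed and defines lexicographic tie-breaking and output column
#' order everywhere in the package.
#'
#' @param letters Character vector of distinct single-character area codes.
#' @return An object of class `area_alphabet` (a character vector).
#' @examples
#' area_alphabet(LETTERS[1:10])
#' @export
area_alphabet <- function(letters = LETTERS[1:10]) {
  letters <- as.character(letters)
  if (length(letters) < 1L) stop("area alphabet must contain at least one area")
  if (length(letters) > 10L) stop("area alphabet supports at most 10 areas")
  if (any(nchar(letters) != 1L))
    stop("area codes must be single characters: ",
         paste(letters[nchar(letters) != 1L], collapse = ", "))
  if (anyDuplicated(letters))
    stop("duplicate area codes: ",
         paste(unique(letters[duplicated(letters)]), collapse = ", "))
  structure(letters, class = "area_alphabet")
}

#' Canonical range key
#'
#' Collapses a set of area letters into the canonical pipe-joined string used
#' throughout the package ("D|E"), with letters ordered by the alphabet.
#'
#' @param letters Character vector of area letters (a set; duplicates dropped).
#' @param alphabet An [area_alphabet()].
#' @return Length-one character string.
#' @export
range_key <- function(letters, alphabet) {
  letters <- unique(as.character(letters))
  idx <- match(letters, alphabet)
  if (anyNA(idx))
    stop("letters outside the area alphabet: ",
         paste(letters[is.na(idx)], collapse = ", "))
  paste(alphabet[sort(idx)], collapse = "|")
}

#' Split a range key back into letters
#' @param key Pipe-joined range string such as "D|E".
#' @return Character vector of letters.
#' @export
range_letters <- function(key) {
  strsplit(key, "|", fixed = TRUE)[[1L]]
}

# basic newick well-formedness scan; reports the 1-based character offset of
# the first structural problem so parse errors are actionable
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  opens <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      depth <- depth + 1L
      opens <- c(opens, i)
    } else if (ch == ")") {
      if (depth == 0L)
        stop("newick syntax error: unmatched ')' at character offset ", i)
      depth <- depth - 1L
      opens <- opens[-length(opens)]
    }
  }
  if (depth > 0L)
    stop("newick syntax error: unmatched '(' at character offset ",
         opens[length(opens)])
  if (!grepl(";", text, fixed = TRUE))
    stop("newick syntax error: missing ';' terminator at character offset ",
         nchar(text) + 1L)
  invisible(TRUE)
}

#' Build a chronogram from an ape phylogeny
#'
#' Validates that the tree is rooted, strictly binary, has positive branch
#' lengths, and is ultrametric within tolerance, then computes node ages
#' measured backward from the present (tips at 0, root at the crown age).
#'
#' @param phy An `ape::phylo` object with branch lengths in Myr.
#' @param tol_factor Ultrametricity tolerance as a fraction of the root age:
#'   the maximum absolute tip age may not exceed `tol_factor * root_age`.
#' @return An object of class `chronogram`: a list with elements `phylo`
#'   (the ape tree), `ages` (node ages in Myr, named by node id, indexed in
#'   ape node order), `node_ids` (tip labels then internal node ids),
#'   `root_age` and `n_tips`.
#' @export
as_chronogram <- function(phy, tol_factor = 1e-6) {
  if (!inherits(phy, "phylo")) stop("expected an ape 'phylo' object")
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop("chronogram needs at least two tips")
  if (!ape::is.rooted(phy)) stop("chronogram must be rooted")
  if (is.null(phy$edge.length))
    stop("chronogram must carry branch lengths (Myr)")
  nnode_total <- ntip + phy$Nnode

  kids <- tabulate(phy$edge[, 1L], nbins = nnode_total)
  bad <- which(kids > 2L)
  if (length(bad))
    stop("polytomy at node ", .node_name(phy, bad[1L]),
         " (", kids[bad[1L]], " children); polytomies are rejected")
  single <- which(kids == 1L)
  if (length(single))
    stop("singleton (unbranched) node ", .node_name(phy, single[1L]),
         " is not allowed")

  if (any(phy$edge.length <= 0))
    stop("all branch lengths must be > 0; offending branch length ",
         format(min(phy$edge.length)))

  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))

  depth <- ape::node.depth.edgelength(phy)
  root_age <- max(depth[seq_len(ntip)])
  ages <- root_age - depth
  dev <- max(abs(ages[seq_len(ntip)]))
  if (dev > tol_factor * root_age)
    stop("tree is not ultrametric: maximum tip-age deviation ",
         format(dev), " Myr exceeds tolerance ",
         format(tol_factor * root_age), " Myr")
  ages[seq_len(ntip)] <- 0

  internal_ids <- if (!is.null(phy$node.label) &&
                      all(nzchar(phy$node.label)) &&
                      !anyDuplicated(phy$node.label)) {
    phy$node.label
  } else {
    sprintf("N%d", (ntip + 1L):nnode_total)
  }
  node_ids <- c(phy$tip.label, internal_ids)
  names(ages) <- node_ids

  structure(
    list(phylo = phy, ages = ages, node_ids = node_ids,
         root_age = root_age, n_tips = ntip),
    class = "chronogram")
}

.node_name <- function(phy, num) {
  ntip <- length(phy$tip.label)
  if (num <= ntip) phy$tip.label[num] else sprintf("N%d", num)
}

#' Parse a chronogram from newick or NEXUS text
#'
#' Accepts a newick string (terminated by `;`) or a NEXUS document containing
#' a TREES block.  The tree must be rooted, binary, ultrametric within
#' tolerance, with positive branch lengths in Myr.  Node ages are computed as
#' the depth of the deepest tip minus each node's depth, so the present is 0
#' and the root carries the crown age.
#'
#' @param text Newick or NEXUS string (or a path to a file holding one).
#' @param tol_factor Ultrametricity tolerance, see [as_chronogram()].
#' @return A `chronogram`.
#' @examples
#' ch <- parse_chronogram("((A:1,B:1):2,(C:2,D:2):1);")
#' ch$root_age      # 3
#' @export
parse_chronogram <- function(text, tol_factor = 1e-6) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("[(;]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  if (grepl("^\\s*#NEXUS", text, ignore.case = TRUE)) {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(text, tf)
    phy <- tryCatch(ape::read.nexus(tf), error = function(e)
      stop("NEXUS parse failure: ", conditionMessage(e)))
    if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  } else {
    .check_newick_syntax(text)
    phy <- tryCatch(ape::read.tree(text = text), error = function(e)
      stop("newick parse failure: ", conditionMessage(e)))
    if (is.null(phy)) stop("newick parse failure: no tree found in input")
    if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  }
  as_chronogram(phy, tol_factor)
}

#' Write a chronogram as plain newick
#' @param chron A `chronogram`.
#' @param file Optional path; when `NULL` the newick string is returned.
#' @export
write_chronogram <- function(chron, file = NULL) {
  stopifnot(inherits(chron, "chronogram"))
  txt <- ape::write.tree(chron$phylo)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

#' @export
print.chronogram <- function(x, ...) {
  cat("chronogram:", x$n_tips, "tips, crown age",
      format(x$root_age, digits = 6), "Myr\n")
  invisible(x)
}

#' Number of lineages crossing a time point
#'
#' Counts branches alive at age `t` under the half-open crossing convention:
#' a branch from parent (age `a_p`) to child (age `a_c`) occupies the
#' interval `(a_p, a_c]`, so a node-age boundary is counted exactly once,
#' with the younger side.  At `t = 0` this equals the tip count; just below
#' the root age it equals 2; at exactly the root age it is 0 (no branch is
#' older than the root).
#'
#' @param chron A `chronogram`.
#' @param t Age in Myr, `0 <= t <= root_age`.
#' @return Integer lineage count.
#' @export
lineages_at <- function(chron, t) {
  stopifnot(inherits(chron, "chronogram"), is.numeric(t), length(t) == 1L)
  if (t < 0 || t > chron$root_age)
    stop("t = ", format(t), " outside [0, root age = ",
         format(chron$root_age), "]")
  edge <- chron$phylo$edge
  pa <- chron$ages[edge[, 1L]]
  ca <- chron$ages[edge[, 2L]]
  sum(pa > t & t >= ca)
}

#' Read taxon-to-areas region codings
#'
#' Reads a two-column delimited table (`taxon,areas` header, comma or tab
#' separated) mapping taxon labels to pipe-separated area letters, e.g.
#' `Sigmodon_hispidus, A|B|D`.  Letters are deduplicated and normalized to
#' alphabet order; empty sets and letters outside the alphabet are rejected.
#'
#' @param x Path to a CSV/TSV file, the text of one, or a data.frame with
#'   columns `taxon` and `areas`.
#' @param alphabet An [area_alphabet()].
#' @return An object of class `region_coding`: a named list of letter
#'   vectors with the alphabet attached as attribute `alphabet`.
#' @export
read_region_codings <- function(x, alphabet) {
  stopifnot(inherits(alphabet, "area_alphabet"))
  if (is.data.frame(x)) {
    df <- x
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    txt <- if (file.exists(x)) paste(readLines(x, warn = FALSE), collapse = "\n") else x
    sep <- if (grepl("\t", strsplit(txt, "\n")[[1L]][1L])) "\t" else ","
    df <- utils::read.table(text = txt, header = TRUE, sep = sep,
                            strip.white = TRUE, colClasses = "character",
                            comment.char = "#")
  }
  names(df) <- tolower(names(df))
  if (!all(c("taxon", "areas") %in% names(df)))
    stop("region coding table must have columns 'taxon' and 'areas'")
  if (anyDuplicated(df$taxon))
    stop("duplicate taxa in region codings: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  assignments <- vector("list", nrow(df))
  names(assignments) <- df$taxon
  for (i in seq_len(nrow(df))) {
    letters <- unique(trimws(strsplit(df$areas[i], "|", fixed = TRUE)[[1L]]))
    letters <- letters[nzchar(letters)]
    if (!length(letters))
      stop("empty area set for taxon '", df$taxon[i], "'")
    unknown <- setdiff(letters, alphabet)
    if (length(unknown))
      stop("unknown area letter '", unknown[1L], "' for taxon '",
           df$taxon[i], "'")
    assignments[[i]] <- alphabet[sort(match(letters, alphabet))]
  }
  structure(assignments, class = "region_coding", alphabet = alphabet)
}

#' Check that a coding and a chronogram name the same taxa
#' @param chron A `chronogram`.
#' @param coding A `region_coding`.
#' @return Invisibly `TRUE`; stops with the offending taxa otherwise.
#' @export
validate_tip_match <- function(chron, coding) {
  tips <- chron$phylo$tip.label
  taxa <- names(coding)
  miss_code <- setdiff(tips, taxa)
  miss_tree <- setdiff(taxa, tips)
  if (length(miss_code) || length(miss_tree))
    stop("taxon mismatch between chronogram and region codings",
         if (length(miss_code)) paste0("; tips without coding: ",
                                       paste(miss_code, collapse = ", ")),
         if (length(miss_tree)) paste0("; coded taxa absent from tree: ",
                                       paste(miss_tree, collapse = ", ")))
  invisible(TRUE)
}

#' Presence/absence matrix of a region coding
#' @param coding A `region_coding`.
#' @param alphabet Optional alphabet; defaults to the coding's own.
#' @return Integer 0/1 matrix, taxa in rows, areas in columns.
#' @export
coding_matrix <- function(coding, alphabet = attr(coding, "alphabet")) {
  m <- matrix(0L, nrow = length(coding), ncol = length(alphabet),
              dimnames = list(names(coding), as.character(alphabet)))
  for (i in seq_along(coding)) m[i, match(coding[[i]], alphabet)] <- 1L
  m
}

#' Write an annotated newick with per-node range comments
#'
#' Emits newick with internal node ids written as node labels and a
#' BEAST-style bracketed comment on every node carrying the MAP range
#' (`[&range=D|E,p=0.93,...]`) plus up to `top_n` range-posterior entries.
#'
#' @param chron A `chronogram`.
#' @param map_ranges Named character vector, node id -> range key, covering
#'   every node.
#' @param range_posteriors Optional named list, node id -> named probability
#'   vector over ranges.
#' @param file Optional output path.
#' @param top_n How many posterior entries to embed per node.
#' @return The newick string (invisibly when `file` is given).
#' @export
write_annotated_newick <- function(chron, map_ranges, range_posteriors = NULL,
                                   file = NULL, top_n = 3L) {
  phy <- chron$phylo
  ntip <- chron$n_tips
  miss <- setdiff(chron$node_ids, names(map_ranges))
  if (length(miss))
    stop("map_ranges missing node(s): ", paste(miss, collapse = ", "))
  edge <- phy$edge
  kids <- split(edge[, 2L], edge[, 1L])
  elen <- numeric(ntip + phy$Nnode)
  elen[edge[, 2L]] <- phy$edge.length
  root <- edge[!(edge[, 1L] %in% edge[, 2L]), 1L][1L]

  ann <- function(id) {
    s <- paste0("[&range=", map_ranges[[id]])
    if (!is.null(range_posteriors) && id %in% names(range_posteriors)) {
      rp <- sort(range_posteriors[[id]], decreasing = TRUE)
      rp <- rp[seq_len(min(top_n, length(rp)))]
      s <- paste0(s, ",p=", signif(rp[1L], 6))
      if (length(rp) > 1L)
        s <- paste0(s, ",alt=",
                    paste(names(rp)[-1L], signif(rp[-1L], 4),
                          sep = ":", collapse = ";"))
    }
    paste0(s, "]")
  }
  rec <- function(num) {
    id <- chron$node_ids[num]
    if (num <= ntip)
      return(paste0(id, ann(id), ":", format(elen[num], digits = 15)))
    inner <- paste(vapply(kids[[as.character(num)]], rec, ""), collapse = ",")
    s <- paste0("(", inner, ")", id, ann(id))
    if (num == root) s else paste0(s, ":", format(elen[num], digits = 15))
  }
  txt <- paste0(rec(root), ";")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read an annotated newick produced by [write_annotated_newick()]
#'
#' @param text Annotated newick string or path to a file holding one.
#' @return A list with elements `chron` (the parsed `chronogram`) and
#'   `assignments` (named character vector, node id -> range key).
#' @export
read_annotated_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("[(;]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  m <- gregexpr("([A-Za-z0-9_.-]+)\\[&range=([^],]+)", text, perl = TRUE)[[1L]]
  pairs <- regmatches(text, gregexpr("([A-Za-z0-9_.-]+)\\[&range=([^],]+)",
                                     text, perl = TRUE))[[1L]]
  if (!length(pairs) || m[1L] == -1L)
    stop("no [&range=...] annotations found")
  labs <- sub("\\[&range=.*$", "", pairs)
  rngs <- sub("^.*\\[&range=", "", pairs)
  stripped <- gsub("\\[&[^]]*\\]", "", text)
  chron <- parse_chronogram(stripped)
  assignments <- stats::setNames(rngs, labs)
  miss <- setdiff(chron$node_ids, names(assignments))
  if (length(miss))
    stop("node(s) without a range annotation: ", paste(miss, collapse = ", "))
  list(chron = chron, assignments = assignments[chron$node_ids])
}

# deterministic substream seeds derived from one master seed
.substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  s <- sample.int(2147483646L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}
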