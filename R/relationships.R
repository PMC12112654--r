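#' Pairwise relationship classification
#'
#' Classifies a within-family pair by the structure of its ancestral paths,
#' not by the kinship value alone (parent-offspring and full siblings both
#' have phi = 1/4 but different path structure). The label vocabulary is the
#' closed set used in family-study relationship tables: lineal
#' (parent-offspring, grandparent-grandchild), collateral full/half
#' (siblings, half-siblings, avuncular, half avuncular, grand avuncular,
#' 1st/2nd cousins with "removed" variants, half 1st cousins) and "double"
#' or compound variants for pairs connected through more than one ancestral
#' couple ("double 1st cousins", "1st cousins and 2nd cousins", ...).
#' Anything deeper than 4th degree, or a compound not in the vocabulary,
#' maps to "other"; cross-family pairs are "unrelated".
#'
#' The relationship degree is derived from the total kinship coefficient as
#' `round(-log2(2 * phi))`, which reproduces the conventional table degrees
#' for both simple and compound relationships (e.g. double 1st cousins,
#' phi = 1/8, are 2nd degree).
#'
#' Path decomposition assumes each pair's joint ancestry is loop-free apart
#' from the connections themselves (no inbred common ancestors); pedigrees
#' violating this fall back to "other" with the kinship-derived degree.
#'
#' @param ped a [pedigree].
#' @param i,j individual ids (within `fid`, if given) or family-qualified
#'   keys.
#' @param fid optional family id qualifying `i` and `j`.
#' @return A list with `degree` (integer, or `"unrelated"`) and
#'   `description` (label string).
#' @examples
#' ped <- pedigree(1, c("f","m","a","b"), c(0,0,"f","f"), c(0,0,"m","m"),
#'                 c(1,2,1,2))
#' classify_pair(ped, "a", "b", fid = 1)$description  # "siblings"
#' @export
classify_pair <- function(ped, i, j, fid = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  ki <- .resolve_key(ped, i, fid)
  kj <- .resolve_key(ped, j, fid)
  if (ki == kj) stop("classify_pair requires two distinct individuals")
  if (ped$fid[match(ki, ped$key)] != ped$fid[match(kj, ped$key)]) {
    return(list(degree = "unrelated", description = "unrelated"))
  }
  idx <- .ped_index(ped)
  .classify_pair_idx(ped, idx, match(ki, ped$key), match(kj, ped$key),
                     phi = NULL)
}

.resolve_key <- function(ped, x, fid) {
  x <- as.character(x)
  if (!is.null(fid)) x <- paste(as.character(fid), x, sep = ":")
  if (x %in% ped$key) return(x)
  hit <- which(ped$id == x)
  if (length(hit) == 1L) return(ped$key[hit])
  if (length(hit) == 0L) stop("unknown individual: ", x)
  stop("ambiguous individual id '", x, "'; qualify with fid")
}

.ped_index <- function(ped) {
  list(
    f = match(ifelse(is.na(ped$father), NA,
                     paste(ped$fid, ped$father, sep = ":")), ped$key),
    m = match(ifelse(is.na(ped$mother), NA,
                     paste(ped$fid, ped$mother, sep = ":")), ped$key)
  )
}

# Ancestors of x: for each ancestor (row index) its depth and the child
# through which the unique path to x descends. inbred = TRUE if some
# ancestor is reachable twice (two distinct paths).
.anc_info <- function(idx, x) {
  depth <- integer(0); via <- integer(0); anc <- integer(0)
  frontier <- x; fdepth <- 0L; fvia <- NA_integer_
  # breadth-first climb; each node carries the child it was reached from
  q_node <- x; q_depth <- 0L; q_child <- x
  inbred <- FALSE
  head <- 1L
  while (head <= length(q_node)) {
    node <- q_node[head]; d <- q_depth[head]; ch <- q_child[head]
    head <- head + 1L
    for (p in c(idx$f[node], idx$m[node])) {
      if (is.na(p)) next
      if (p %in% anc) inbred <- TRUE
      anc <- c(anc, p); depth <- c(depth, d + 1L); via <- c(via, node)
      q_node <- c(q_node, p); q_depth <- c(q_depth, d + 1L)
      q_child <- c(q_child, node)
    }
  }
  list(anc = anc, depth = depth, via = via, inbred = inbred)
}

.classify_pair_idx <- function(ped, idx, a, b, phi = NULL) {
  ai <- .anc_info(idx, a)
  bi <- .anc_info(idx, b)

  kin <- if (is.null(phi)) NULL else phi[a, b]
  degree_from_phi <- function(ph) {
    if (ph <= 0) return("unrelated")
    as.integer(round(-log2(2 * ph)))
  }
  phi_pair <- function() {
    if (!is.null(kin)) return(kin)
    # kinship of just this pair via path counting (non-inbred assumption not
    # needed: recompute from scratch on the family block)
    fam <- ped$fid[a]
    sub <- which(ped$fid == fam)
    kf <- kinship_matrix(ped[sub, , drop = FALSE])
    kf$phi[match(ped$key[a], kf$key), match(ped$key[b], kf$key)]
  }

  # lineal?
  if (a %in% bi$anc) {
    g <- min(bi$depth[bi$anc == a])
    lab <- if (g == 1L) "parent-offspring" else
           if (g == 2L) "grandparent-grandchild" else "other"
    return(list(degree = g, description = lab))
  }
  if (b %in% ai$anc) {
    g <- min(ai$depth[ai$anc == b])
    lab <- if (g == 1L) "parent-offspring" else
           if (g == 2L) "grandparent-grandchild" else "other"
    return(list(degree = g, description = lab))
  }

  ca <- intersect(ai$anc, bi$anc)
  if (!length(ca)) return(list(degree = "unrelated", description = "unrelated"))

  if (ai$inbred || bi$inbred ||
      anyDuplicated(ai$anc) || anyDuplicated(bi$anc)) {
    ph <- phi_pair()
    return(list(degree = degree_from_phi(ph), description = "other"))
  }

  # connection apexes: common ancestors whose paths to a and b diverge
  # immediately (same connecting child => a nearer common ancestor exists)
  da <- ai$depth[match(ca, ai$anc)]
  db <- bi$depth[match(ca, bi$anc)]
  via_a <- ai$via[match(ca, ai$anc)]
  via_b <- bi$via[match(ca, bi$anc)]
  apex <- via_a != via_b
  ca <- ca[apex]; da <- da[apex]; db <- db[apex]
  via_a <- via_a[apex]; via_b <- via_b[apex]
  if (!length(ca)) {
    ph <- phi_pair()
    return(list(degree = degree_from_phi(ph), description = "other"))
  }

  # group apexes by the (child-toward-a, child-toward-b) junction:
  # two mates sharing a junction form one "full" connection, a lone
  # ancestor a "half" connection
  junction <- paste(via_a, via_b)
  comps <- lapply(split(seq_along(ca), junction), function(ix) {
    list(a = min(da[ix]), b = min(db[ix]), full = length(ix) >= 2L)
  })
  labels <- vapply(comps, function(cp) {
    lo <- min(cp$a, cp$b); hi <- max(cp$a, cp$b)
    .collateral_label(lo, hi, cp$full)
  }, character(1))

  ph <- phi_pair()
  deg <- degree_from_phi(ph)
  desc <-
    if (length(labels) == 1L) labels[[1]]
    else if (length(labels) == 2L && labels[1] == labels[2])
      paste("double", labels[1])
    else if (length(labels) == 2L)
      paste(sort(labels), collapse = " and ")
    else "other"
  if (!(desc %in% relationship_vocabulary())) desc <- "other"
  if (is.numeric(deg) && deg >= 5L) desc <- "other"
  list(degree = deg, description = desc)
}

# label for a single collateral connection with apex depths (lo <= hi)
.collateral_label <- function(lo, hi, full) {
  base <-
    if (lo == 1L && hi == 1L) "siblings"
    else if (lo == 1L && hi == 2L) "avuncular"
    else if (lo == 1L && hi == 3L) "grand avuncular"
    else if (lo == 1L) "other"
    else {
      ord <- lo - 1L
      rem <- hi - lo
      nm <- paste0(.ordinal(ord), " cousins")
      if (rem > 0) nm <- paste0(nm, ", ", rem, " removed")
      nm
    }
  if (!full) {
    base <- if (base == "siblings") "half-siblings" else paste("half", base)
  }
  base
}

.ordinal <- function(k) {
  suf <- if (k %% 10 == 1 && k != 11) "st" else
         if (k %% 10 == 2 && k != 12) "nd" else
         if (k %% 10 == 3 && k != 13) "rd" else "th"
  paste0(k, suf)
}

#' Closed vocabulary of relationship labels
#'
#' The labels emitted by [classify_pair()], mirroring the rows of a standard
#' family-study relationship table: simple lineal and collateral labels,
#' "double" variants (two ancestral couples), and composite rows for pairs
#' related two different ways. Everything else collapses to "other".
#'
#' @return character vector of labels.
#' @export
relationship_vocabulary <- function() {
  c("parent-offspring", "siblings",
    "grandparent-grandchild", "avuncular", "half-siblings",
    "double 1st cousins",
    "1st cousins and 2nd cousins", "grand avuncular", "half avuncular",
    "1st cousins", "double 1st cousins, 1 removed",
    "1st cousins, 1 removed and 2nd cousins, 1 removed",
    "1st cousins, 1 removed", "half 1st cousins", "double 2nd cousins",
    "double 1st cousins, 2 removed",
    "other", "unrelated")
}

#' Count pairwise relationships in a pedigree
#'
#' Classifies every within-family pair exactly once and tabulates by
#' (degree, description). Spouse-like pairs with zero kinship count as
#' "unrelated"; the total number of relative pairs excludes them.
#'
#' @param ped a [pedigree].
#' @return data frame with columns `degree`, `description`, `n_pairs`, with
#'   attribute `total_relative_pairs` = sum of `n_pairs` over related rows.
#'   The grand total over all rows (related + unrelated) equals
#'   `sum(n_f * (n_f - 1) / 2)` over family sizes `n_f`.
#' @seealso [relationship_total()] for the total-row logic on a saved table.
#' @export
count_relationships <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  idx <- .ped_index(ped)
  kin <- kinship_matrix(ped)
  rows <- list()
  for (fam in unique(ped$fid)) {
    members <- which(ped$fid == fam)
    nf <- length(members)
    if (nf < 2) next
    for (u in seq_len(nf - 1)) {
      for (v in seq(u + 1, nf)) {
        cl <- .classify_pair_idx(ped, idx, members[u], members[v],
                                 phi = kin$phi)
        rows[[length(rows) + 1L]] <- data.frame(
          degree = as.character(cl$degree), description = cl$description,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(degree = character(0), description = character(0),
                      n_pairs = integer(0))
    attr(out, "total_relative_pairs") <- 0L
    return(out)
  }
  all <- do.call(rbind, rows)
  tab <- stats::aggregate(list(n_pairs = rep(1L, nrow(all))),
                          by = list(degree = all$degree,
                                    description = all$description),
                          FUN = sum)
  ordkey <- suppressWarnings(as.integer(tab$degree))
  tab <- tab[order(is.na(ordkey), ordkey, tab$description), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "total_relative_pairs") <- relationship_total(tab)
  tab
}

#' Total relative pairs in a relationship count table
#'
#' Sums `n_pairs` over all labelled relationship rows, excluding "unrelated"
#' pairs and any pre-existing total row. This is the "total relative pairs"
#' figure of a relationship table.
#'
#' @param counts data frame with columns `description` and `n_pairs`.
#' @return integer total.
#' @export
relationship_total <- function(counts) {
  stopifnot(all(c("description", "n_pairs") %in% names(counts)))
  keep <- !(tolower(counts$description) %in%
              c("unrelated", "total relative pairs", "total"))
  as.integer(sum(counts$n_pairs[keep]))
}

#' Write a relationship count table as TSV
#'
#' Columns: degree, description, n_pairs, plus a final total row.
#'
#' @param counts output of [count_relationships()].
#' @param path output path.
#' @export
write_relationship_counts <- function(counts, path) {
  out <- counts
  out <- rbind(out, data.frame(degree = "", description = "total relative pairs",
                               n_pairs = relationship_total(counts)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
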