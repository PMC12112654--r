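#' Pedigree construction and validation
#'
#' A `pedigree` is a validated data frame of individuals with parent links,
#' partitioned into families. Parents must either both be present or both be
#' absent (coded `"0"`/`NA`); parent ids must resolve within the same family;
#' the parent graph must be acyclic.
#'
#' @param fid character/integer family identifiers.
#' @param id individual identifiers, unique within family.
#' @param father,mother parent identifiers; `"0"`, `""` or `NA` mean missing.
#' @param sex sex codes: 1/"1"/"M"/"male" = male, 2/"2"/"F"/"female" = female,
#'   anything else (including 0/NA) = unknown.
#' @return An object of class `pedigree`: a data frame with columns
#'   `fid`, `id`, `father`, `mother`, `sex` (factor male/female/unknown),
#'   `founder` (logical), ordered so that parents precede offspring within
#'   each family, with a `key` column of family-qualified ids.
#' @examples
#' ped <- pedigree(fid = c(1, 1, 1, 1), id = c("a", "b", "c", "d"),
#'                 father = c(0, 0, "a", "a"), mother = c(0, 0, "b", "b"),
#'                 sex = c(1, 2, 1, 2))
#' summary(ped)
#' @export
pedigree <- function(fid, id, father, mother, sex = NULL) {
  n <- length(id)
  if (length(fid) == 1L) fid <- rep(fid, n)
  stopifnot(length(fid) == n, length(father) == n, length(mother) == n)
  fid <- as.character(fid)
  id <- as.character(id)
  father <- .norm_parent(father)
  mother <- .norm_parent(mother)
  if (is.null(sex)) sex <- rep(NA, n)
  sex <- .norm_sex(sex)

  key <- paste(fid, id, sep = ":")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicated individual id within family: ",
         paste(unique(id[dup]), collapse = ", "))
  }
  half <- xor(is.na(father), is.na(mother))
  if (any(half)) {
    stop("half-specified parents (one parent id missing) for: ",
         paste(id[half], collapse = ", "),
         "; add a dummy founder for the unknown parent")
  }
  fkey <- ifelse(is.na(father), NA, paste(fid, father, sep = ":"))
  mkey <- ifelse(is.na(mother), NA, paste(fid, mother, sep = ":"))
  bad_f <- !is.na(fkey) & !(fkey %in% key)
  bad_m <- !is.na(mkey) & !(mkey %in% key)
  if (any(bad_f | bad_m)) {
    stop("unresolved parent id within family for individual(s): ",
         paste(id[bad_f | bad_m], collapse = ", "))
  }
  self_par <- !is.na(father) & (father == id | mother == id)
  if (any(self_par)) {
    stop("cycle detected in pedigree at individual: ",
         paste(id[self_par], collapse = ", "))
  }

  ped <- data.frame(fid = fid, id = id, father = father, mother = mother,
                    sex = sex, stringsAsFactors = FALSE)
  ped$key <- key
  ped$founder <- is.na(father)
  ord <- .toposort(ped)           # errors on cycles
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

.norm_parent <- function(x) {
  x <- as.character(x)
  x[x %in% c("0", "", "NA") | is.na(x)] <- NA
  x
}

.norm_sex <- function(sex) {
  s <- tolower(as.character(sex))
  out <- rep("unknown", length(s))
  out[s %in% c("1", "m", "male")] <- "male"
  out[s %in% c("2", "f", "female")] <- "female"
  factor(out, levels = c("male", "female", "unknown"))
}

# Kahn topological sort over parent->child edges, family by family.
# Errors with the offending individual if a cycle exists.
.toposort <- function(ped) {
  n <- nrow(ped)
  fidx <- match(ifelse(is.na(ped$father), NA,
                       paste(ped$fid, ped$father, sep = ":")), ped$key)
  midx <- match(ifelse(is.na(ped$mother), NA,
                       paste(ped$fid, ped$mother, sep = ":")), ped$key)
  indeg <- (!is.na(fidx)) + (!is.na(midx))
  children <- vector("list", n)
  for (k in seq_len(n)) {
    for (p in c(fidx[k], midx[k])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], k)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    k <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, k)
    for (ch in children[[k]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    left <- setdiff(seq_len(n), ord)
    stop("cycle detected in pedigree at individual: ", ped$id[left[1L]])
  }
  ord
}

#' @export
summary.pedigree <- function(object, ...) {
  sizes <- table(object$fid)
  founders <- tapply(object$founder, object$fid, sum)
  out <- list(
    n = nrow(object),
    n_families = length(sizes),
    family_sizes = as.integer(sizes),
    founders_per_family = as.integer(founders),
    size_summary = c(mean = mean(as.integer(sizes)),
                     median = stats::median(as.integer(sizes)),
                     max = max(as.integer(sizes)))
  )
  class(out) <- "summary.pedigree"
  out
}

#' @export
print.summary.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individuals in %d families\n", x$n, x$n_families))
  cat(sprintf("  family size mean %.2f, median %g, max %d\n",
              x$size_summary["mean"], x$size_summary["median"],
              max(x$family_sizes)))
  cat(sprintf("  founders %d, non-founders %d\n",
              sum(x$founders_per_family),
              x$n - sum(x$founders_per_family)))
  invisible(x)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals, %d families\n",
              nrow(x), length(unique(x$fid))))
  print.data.frame(utils::head(as.data.frame(x)[,
    c("fid", "id", "father", "mother", "sex")], 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Read a pedigree from a PLINK/LINKAGE .fam file
#'
#' Whitespace-delimited columns: family id, individual id, father id,
#' mother id, sex (1 = male, 2 = female, other = unknown). Extra columns
#' (e.g. the .fam phenotype column) are ignored. `"0"` codes a missing
#' parent. Validation (cycles, unresolved or half-specified parents,
#' duplicate ids) is performed by [pedigree()].
#'
#' @param path file path.
#' @return A [pedigree] object. Founder/non-founder counts per family are
#'   available through `summary()`.
#' @seealso [write_pedigree()]
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 4) stop("pedigree file needs >= 4 columns (fid id father mother)")
  sex <- if (ncol(tab) >= 5) tab[[5]] else NULL
  pedigree(fid = tab[[1]], id = tab[[2]], father = tab[[3]],
           mother = tab[[4]], sex = sex)
}

#' Write a pedigree as a PLINK .fam file
#'
#' Sex is written as 1/2/0; missing parents as "0"; the phenotype column is
#' written as "-9". Round-trips losslessly through [read_pedigree()].
#'
#' @param ped a [pedigree].
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  sexcode <- c(male = 1L, female = 2L, unknown = 0L)[as.character(ped$sex)]
  out <- data.frame(ped$fid, ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    sexcode, -9L)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' Kinship matrix from a pedigree
#'
#' Computes kinship coefficients phi_ij by the standard recursion in
#' topological order: founders have phi_ii = 1/2 and phi_ij = 0 among
#' themselves; a non-founder k with parents f and m has
#' phi_kk = (1 + phi_fm) / 2 and phi_kj = (phi_fj + phi_mj) / 2 for any j
#' processed before k. Across families phi is exactly zero, so 2*phi — the
#' expected additive genetic relationship used in variance-component models —
#' is block-diagonal by family and positive semi-definite.
#'
#' @param ped a [pedigree].
#' @return Object of class `kinship_matrix`: list with `phi` (dense symmetric
#'   matrix, dimnames = family-qualified keys), `ids`, `fid`.
#' @examples
#' ped <- pedigree(1, c("f","m","c"), c(0,0,"f"), c(0,0,"m"), c(1,2,1))
#' kinship_matrix(ped)$phi["1:f", "1:c"]   # 0.25
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$key, ped$key))
  fidx <- match(ifelse(is.na(ped$father), NA,
                       paste(ped$fid, ped$father, sep = ":")), ped$key)
  midx <- match(ifelse(is.na(ped$mother), NA,
                       paste(ped$fid, ped$mother, sep = ":")), ped$key)
  # pedigree rows are already topologically sorted
  same_fam <- function(k) which(ped$fid == ped$fid[k])
  for (k in seq_len(n)) {
    if (is.na(fidx[k])) {
      phi[k, k] <- 0.5
    } else {
      f <- fidx[k]; m <- midx[k]
      phi[k, k] <- 0.5 * (1 + phi[f, m])
      js <- same_fam(k)
      js <- js[js < k]
      if (length(js)) {
        v <- 0.5 * (phi[f, js] + phi[m, js])
        phi[k, js] <- v
        phi[js, k] <- v
      }
    }
  }
  structure(list(phi = phi, ids = ped$id, fid = ped$fid, key = ped$key),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d individuals, %d families\n",
              length(x$ids), length(unique(x$fid))))
  invisible(x)
}

#' Subset a kinship matrix to a set of individuals
#'
#' Used to align the (full-pedigree) kinship matrix with the individuals that
#' actually enter a likelihood: relatedness among the retained individuals is
#' preserved because phi was computed on the complete pedigree first.
#'
#' @param kin a `kinship_matrix`.
#' @param keys family-qualified keys (`kin$key` entries) to retain, in order.
#' @export
subset_kinship <- function(kin, keys) {
  stopifnot(inherits(kin, "kinship_matrix"))
  idx <- match(keys, kin$key)
  if (anyNA(idx)) stop("unknown individual keys in subset_kinship")
  structure(list(phi = kin$phi[idx, idx, drop = FALSE],
                 ids = kin$ids[idx], fid = kin$fid[idx], key = kin$key[idx]),
            class = "kinship_matrix")
}
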