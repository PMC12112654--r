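#' Rank-based inverse normal transformation
#'
#' Maps a quantitative vector to normal scores
#' `qnorm((rank - c) / (n - 2c + 1))` with average ranks for ties and
#' missing values preserved. The default offset `c = 3/8` (Blom) gives
#' `qnorm((rank - 3/8) / (n + 1/4))`; `method = "vdw"` uses the
#' van der Waerden offset `c = 0`.
#'
#' @param x numeric vector, at least 3 non-missing values.
#' @param method `"blom"` (default) or `"vdw"`.
#' @return transformed vector, same length and missingness pattern as `x`.
#' @examples
#' inverse_normal(c(1, 2, 3))   # -0.8694 0 0.8694
#' @export
inverse_normal <- function(x, method = c("blom", "vdw")) {
  method <- match.arg(method)
  ok <- !is.na(x)
  if (!any(ok)) stop("inverse_normal: all values missing")
  if (sum(ok) < 3) stop("inverse_normal: need >= 3 non-missing values")
  cc <- switch(method, blom = 3 / 8, vdw = 0)
  n <- sum(ok)
  r <- rank(x[ok], ties.method = "average")
  out <- x
  out[ok] <- stats::qnorm((r - cc) / (n - 2 * cc + 1))
  out
}

#' Natural log transformation
#'
#' @param x numeric vector; all non-missing values must be strictly positive.
#' @param ids optional identifiers used in the error message.
#' @return `log(x)` elementwise, missing preserved.
#' @export
log_transform <- function(x, ids = NULL) {
  bad <- !is.na(x) & x <= 0
  if (any(bad)) {
    who <- if (is.null(ids)) which(bad) else ids[bad]
    stop("log_transform: non-positive value(s) for: ",
         paste(who, collapse = ", "))
  }
  log(x)
}

#' Mean arterial pressure
#'
#' `MAP = DBP + (SBP - DBP) / 3`, in mmHg. Always lies between DBP and SBP.
#'
#' @param sbp,dbp systolic and diastolic blood pressure (mmHg), `sbp >= dbp > 0`.
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  bad <- !is.na(sbp) & !is.na(dbp) & (sbp < dbp | dbp <= 0)
  if (any(bad)) stop("mean_arterial_pressure: need sbp >= dbp > 0")
  dbp + (sbp - dbp) / 3
}

#' Steatosis classification from liver fat fraction
#'
#' Dichotomizes MRI proton-density fat fraction at the clinically significant
#' cut-point of 5.56 percent (inclusive: a value exactly at the cut-point
#' classifies as steatosis).
#'
#' @param pdff liver fat fraction in percent, `>= 0`.
#' @param cutpoint cut-point in percent.
#' @return integer 0/1 vector.
#' @export
classify_steatosis <- function(pdff, cutpoint = 5.56) {
  if (any(!is.na(pdff) & pdff < 0)) stop("classify_steatosis: pdff must be >= 0")
  as.integer(pdff >= cutpoint)
}

#' HOMA-IR from fasting glucose and insulin
#'
#' Homeostatic model assessment of insulin resistance, using the
#' conventional US-units form glucose(mg/dL) x insulin(uU/mL) / 405.
#' The constant is an assumption of this helper (cohorts differ in the
#' units convention); HOMA-IR may equally be supplied as a ready-made
#' trait column.
#'
#' @param glucose fasting glucose, mg/dL.
#' @param insulin fasting insulin, uU/mL.
#' @param constant divisor, default 405.
#' @export
homa_ir <- function(glucose, insulin, constant = 405) {
  glucose * insulin / constant
}

#' Covariate design matrix: intercept, age, sex, age x sex
#'
#' Age is mean-centered over the supplied individuals (so the intercept is
#' the mean at average age in the reference sex). Individuals with a missing
#' covariate are excluded and reported via the `excluded` attribute;
#' constant columns (e.g. single-sex data) are flagged `collinear`.
#'
#' @param ids individual identifiers.
#' @param age numeric, years.
#' @param sex 0/1 numeric (or a factor coercible to 0/1).
#' @return numeric matrix with columns `(Intercept)`, `age_c`, `sex`,
#'   `age_c:sex` and rownames `ids`; attributes `excluded` (ids dropped for
#'   missing covariates) and `collinear` (names of constant columns).
#' @export
covariate_design <- function(ids, age, sex) {
  ids <- as.character(ids)
  if (is.factor(sex)) sex <- as.numeric(sex) - 1
  sex <- as.numeric(sex)
  keep <- !is.na(age) & !is.na(sex)
  excluded <- ids[!keep]
  age <- age[keep]; sex <- sex[keep]; ids <- ids[keep]
  age_c <- age - mean(age)
  X <- cbind(`(Intercept)` = 1, age_c = age_c, sex = sex,
             `age_c:sex` = age_c * sex)
  rownames(X) <- ids
  collinear <- colnames(X)[-1][apply(X[, -1, drop = FALSE], 2,
                                     function(cl) length(unique(cl)) < 2)]
  attr(X, "excluded") <- excluded
  attr(X, "collinear") <- collinear
  X
}

#' Apply a transformation plan to a trait table
#'
#' A plan maps trait name to one of `"none"`, `"log"`, `"inverse_normal"`;
#' it can be given as a named character vector or list, or read from a
#' YAML/JSON file with [read_transform_plan()]. Traits not named in the plan
#' are left untouched.
#'
#' @param traits data frame of traits; non-trait columns (`id`, `age`,
#'   `sex`) are passed through.
#' @param plan named character vector/list: trait -> transform.
#' @return data frame with transformed trait columns.
#' @export
apply_transforms <- function(traits, plan) {
  plan <- unlist(plan)
  unknown <- setdiff(names(plan), names(traits))
  if (length(unknown)) stop("transform plan names unknown traits: ",
                            paste(unknown, collapse = ", "))
  for (tr in names(plan)) {
    traits[[tr]] <- switch(as.character(plan[[tr]]),
      none = traits[[tr]],
      log = log_transform(traits[[tr]], ids = traits$id),
      inverse_normal = inverse_normal(traits[[tr]]),
      stop("unknown transform '", plan[[tr]], "' for trait ", tr))
  }
  traits
}

#' Read a transformation plan from YAML or JSON
#'
#' @param path file mapping trait names to `none` / `log` / `inverse_normal`.
#' @return named character vector.
#' @export
read_transform_plan <- function(path) {
  plan <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unlist(plan)
}

#' Read/write a trait table as TSV
#'
#' Tab-separated with header; missing values coded `NA`. The first column
#' must be `id`; `age` and `sex` are conventional covariate columns.
#'
#' @param path file path.
#' @export
read_traits <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA")
  if (names(tab)[1] != "id") stop("trait table must start with an 'id' column")
  tab$id <- as.character(tab$id)
  tab
}

#' @rdname read_traits
#' @param traits data frame with an `id` column.
#' @export
write_traits <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
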