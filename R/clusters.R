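#' Normalise ICD-10 codes
#'
#' Brings raw ICD-10 strings into the canonical dotless form used throughout
#' the package: uppercase, the dot after the third character removed
#' (`"J21.9"` becomes `"J219"`), surrounding whitespace stripped. A valid
#' code is one letter, two digits, then optional alphanumeric characters.
#'
#' @param raw Character vector of raw codes.
#' @return Character vector of normalised codes.
#' @examples
#' normalise_code(c("j21.9", "G47.3", " A37"))
#' @export
normalise_code <- function(raw) {
  if (length(raw) == 0L) return(character())
  if (!is.character(raw)) raw <- as.character(raw)
  out <- toupper(gsub(".", "", trimws(raw), fixed = TRUE))
  bad <- is.na(out) | !grepl("^[A-Z][0-9]{2}[A-Z0-9]*$", out)
  if (any(bad)) {
    stop("invalid ICD-10 code(s): ",
         paste(unique(raw[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Define a named ICD-10 code cluster
#'
#' A cluster is a named set of ICD-10 codes and inclusive ranges with
#' prefix-matching semantics. Members can be:
#' * a 3-character code such as `"A37"`, matching the code and all subcodes;
#' * an inclusive range of 3-character stems such as `"J00-J22"`;
#' * a 4+-character code such as `"G47.3"`/`"G473"`, matching itself and any
#'   deeper subcode, but not its siblings (`"G474"` does not match).
#'
#' @param name Cluster name.
#' @param members Character vector of codes or `"start-end"` ranges.
#' @return An object of class `code_cluster`.
#' @examples
#' rti <- code_cluster("rti", c("A37", "J00-J22"))
#' code_in_cluster(c("J219", "J45", "A370"), rti)
#' @export
code_cluster <- function(name, members) {
  stopifnot(is.character(name), length(name) == 1L, length(members) >= 1L)
  is_range <- grepl("-", members, fixed = TRUE)
  parts <- strsplit(members[is_range], "-", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed range in cluster '", name, "'", call. = FALSE)
  }
  lo <- normalise_code(vapply(parts, `[`, "", 1L))
  hi <- normalise_code(vapply(parts, `[`, "", 2L))
  if (any(nchar(lo) != 3L | nchar(hi) != 3L)) {
    stop("range endpoints must be 3-character stems in cluster '", name, "'",
         call. = FALSE)
  }
  if (any(lo > hi)) {
    stop("range start exceeds end in cluster '", name, "'", call. = FALSE)
  }
  single <- normalise_code(members[!is_range])
  structure(
    list(
      name     = name,
      members  = members,
      lo       = c(lo, substr(single[nchar(single) == 3L], 1L, 3L)),
      hi       = c(hi, single[nchar(single) == 3L]),
      prefixes = single[nchar(single) >= 4L]
    ),
    class = "code_cluster"
  )
}

#' @export
print.code_cluster <- function(x, ...) {
  cat("<code_cluster> ", x$name, ": ", paste(x$members, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Test cluster membership of ICD-10 codes
#'
#' @param codes Character vector of normalised codes (see [normalise_code()]).
#' @param cluster A [code_cluster()].
#' @return Logical vector: `TRUE` where the code's 3-character stem falls in a
#'   member range (or equals a 3-character member), or a 4+-character member
#'   is a prefix of the code.
#' @export
code_in_cluster <- function(codes, cluster) {
  stopifnot(inherits(cluster, "code_cluster"))
  if (length(codes) == 0L) return(logical())
  stem <- substr(codes, 1L, 3L)
  hit <- rep(FALSE, length(codes))
  for (i in seq_along(cluster$lo)) {
    hit <- hit | (stem >= cluster$lo[i] & stem <= cluster$hi[i])
  }
  for (p in cluster$prefixes) {
    hit <- hit | startsWith(codes, p)
  }
  hit
}

#' The acute-RTI code cluster
#'
#' ICD-10 A37 (whooping cough) plus J00-J22, codes specific for acute
#' respiratory tract infections.
#'
#' @return A [code_cluster()].
#' @export
cluster_rti <- function() {
  code_cluster("rti", c("A37", "J00-J22"))
}

#' The sensitive any-respiratory code cluster
#'
#' A broader cluster indicating any respiratory condition, including RTIs:
#' A37, J00-J99, R05, R06, E84, P75, Q30-Q34, Q790, G47.3, P22-P28. Estimates
#' based on this cluster bound the RTI-specific ones from above.
#'
#' @return A [code_cluster()].
#' @export
cluster_respiratory <- function() {
  code_cluster("respiratory",
               c("A37", "J00-J99", "R05", "R06", "E84", "P75",
                 "Q30-Q34", "Q790", "G473", "P22-P28"))
}

#' Names of the eight chronic-condition groups
#' @return Character vector of length 8 (fixed order).
#' @export
chronic_group_names <- function() {
  c("mental_behavioural",
    "cancer_blood",
    "chronic_infection",
    "respiratory",
    "endocrine_metabolic_renal_digestive_genitourinary",
    "musculoskeletal_skin",
    "neurological_sensory",
    "cardiac")
}

#' Exemplar chronic-condition code groups
#'
#' Chronic conditions (any condition requiring a year or more of medical
#' follow-up) are grouped into eight fixed categories. The authoritative
#' published code list is not redistributable, so the package ships editable
#' exemplar ranges per group; every group-level output is a function of this
#' configuration.
#'
#' @param overrides Optional named list of character vectors replacing the
#'   member list of the named group(s).
#' @return Named list of eight [code_cluster()] objects (class
#'   `chronic_groups`).
#' @export
chronic_groups_default <- function(overrides = NULL) {
  members <- list(
    mental_behavioural = c("F00-F99"),
    cancer_blood       = c("C00-C97", "D00-D48", "D55-D89"),
    chronic_infection  = c("B20-B24", "B90-B94"),
    respiratory        = c("J40-J47", "J80-J84", "J96", "E84", "P27"),
    endocrine_metabolic_renal_digestive_genitourinary =
      c("E00-E83", "E85-E90", "K50-K93", "N00-N39", "Q60-Q64"),
    musculoskeletal_skin = c("L00-L99", "M00-M99", "Q65-Q79"),
    neurological_sensory = c("G00-G99", "H00-H95", "Q00-Q07"),
    cardiac              = c("I00-I52", "Q20-Q28")
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), all(names(overrides) %in% names(members)))
    members[names(overrides)] <- overrides
  }
  chronic_groups(lapply(names(members), function(g) {
    code_cluster(g, members[[g]])
  }))
}

#' Validate a set of chronic-condition groups
#'
#' @param groups List of eight [code_cluster()] objects named (or nameable)
#'   after [chronic_group_names()], in that order.
#' @return The validated list with class `chronic_groups`.
#' @export
chronic_groups <- function(groups) {
  want <- chronic_group_names()
  if (length(groups) != 8L) {
    stop("exactly eight chronic-condition groups are required", call. = FALSE)
  }
  cl_names <- vapply(groups, function(g) g$name, "")
  if (!setequal(cl_names, want)) {
    stop("chronic group names must be exactly: ",
         paste(want, collapse = ", "), call. = FALSE)
  }
  groups <- groups[match(want, cl_names)]
  names(groups) <- want
  structure(groups, class = c("chronic_groups", "list"))
}
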