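CODE_TIERS <- c("SPECIFICITY", "SENSITIVITY_EXT")
CODE_ROLES <- c("EVENT", "TRAUMA", "SAME_LEVEL_FALL", "RAD_CONTEXT")

#' Build a codebook from an entry table
#'
#' A codebook maps code patterns to SRE subtypes, tiers and roles. Patterns
#' are normalized codes, optionally ending in `*` to match any code with that
#' prefix; a trailing `X`/`x` on an ICD-9 pattern (the handbook's `733.1X`
#' notation) is accepted as a synonym and converted on load, since ICD-9-CM
#' codes never legitimately end in X.
#'
#' Roles: `EVENT` entries identify SRE subtype claims and carry a tier
#' (`SPECIFICITY` for the high-specificity list, `SENSITIVITY_EXT` for the
#' codes the high-sensitivity list *adds*, so sensitivity = union by
#' construction); `TRAUMA` marks external-cause codes for accidents and falls
#' that void a nearby "other fracture"; `SAME_LEVEL_FALL` marks the exempt
#' low-energy fall codes; `RAD_CONTEXT` marks diagnoses (bone metastasis,
#' bone pain) that satisfy the optional radiation concurrency filter.
#'
#' @param entries data.frame with columns `pattern, system, sre_type, tier,
#'   role`. `sre_type` must be one of PF/SCC/RAD/BS for `EVENT` rows and
#'   `NONE` (or blank) otherwise.
#' @return A data.frame of class `"sre_codebook"` with validated, normalized
#'   entries.
#' @export
codebook <- function(entries) {
  req <- c("pattern", "system", "sre_type", "tier", "role")
  missing <- setdiff(req, names(entries))
  if (length(missing)) {
    stop("codebook is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cb <- as.data.frame(lapply(entries[req], as.character),
                      stringsAsFactors = FALSE)
  cb$sre_type[!nzchar(trimws(cb$sre_type))] <- "NONE"
  cb$tier[!nzchar(trimws(cb$tier))] <- "SPECIFICITY"

  problems <- character()
  if (any(!cb$system %in% CODE_SYSTEMS)) {
    problems <- c(problems, paste("unknown system at row(s)",
      paste(which(!cb$system %in% CODE_SYSTEMS), collapse = ", ")))
  }
  if (any(!cb$role %in% CODE_ROLES)) {
    problems <- c(problems, paste("unknown role at row(s)",
      paste(which(!cb$role %in% CODE_ROLES), collapse = ", ")))
  }
  if (any(!cb$tier %in% CODE_TIERS)) {
    problems <- c(problems, paste("unknown tier at row(s)",
      paste(which(!cb$tier %in% CODE_TIERS), collapse = ", ")))
  }
  if (any(!cb$sre_type %in% c(SRE_TYPES, "NONE"))) {
    problems <- c(problems, paste("unknown sre_type at row(s)",
      paste(which(!cb$sre_type %in% c(SRE_TYPES, "NONE")), collapse = ", ")))
  }
  bad_event <- cb$role == "EVENT" & cb$sre_type == "NONE"
  if (any(bad_event)) {
    problems <- c(problems, paste("role EVENT requires an sre_type at row(s)",
      paste(which(bad_event), collapse = ", ")))
  }
  bad_aux <- cb$role != "EVENT" & cb$sre_type != "NONE"
  if (any(bad_aux)) {
    problems <- c(problems, paste("non-EVENT roles must have sre_type NONE at row(s)",
      paste(which(bad_aux), collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid codebook: ", paste(problems, collapse = "; "), call. = FALSE)
  }

  # normalize patterns; accept trailing X as wildcard on ICD-9 patterns
  wild <- endsWith(cb$pattern, "*")
  stem <- ifelse(wild, substr(cb$pattern, 1, nchar(cb$pattern) - 1), cb$pattern)
  stem <- normalize_code(stem)
  icd9_x <- !wild & startsWith(cb$system, "ICD9") & endsWith(stem, "X")
  stem[icd9_x] <- substr(stem[icd9_x], 1, nchar(stem[icd9_x]) - 1)
  wild <- wild | icd9_x
  cb$prefix <- stem
  cb$wildcard <- wild
  cb$pattern <- paste0(stem, ifelse(wild, "*", ""))

  key <- paste(cb$pattern, cb$system, cb$role, cb$sre_type, sep = "\r")
  if (anyDuplicated(key)) {
    stop("invalid codebook: duplicate (pattern, system, role, sre_type) at row(s) ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  }
  cb <- cb[order(match(cb$sre_type, c(SRE_TYPES, "NONE")),
                 match(cb$tier, CODE_TIERS), cb$role, cb$pattern, cb$system), ]
  rownames(cb) <- NULL
  class(cb) <- c("sre_codebook", "data.frame")
  cb
}

#' Load a codebook from a delimited file
#'
#' @param path CSV with columns `pattern, system, sre_type, tier, role`.
#' @return An `"sre_codebook"` object (see [codebook()]).
#' @export
load_codebook <- function(path) {
  codebook(utils::read.csv(path, colClasses = "character"))
}

#' The default SRE codebook
#'
#' The code lists named in the study text, shipped as
#' `inst/extdata/default_codebook.csv`:
#' \itemize{
#'   \item PF high specificity: 733.1X "pathologic fracture" diagnoses.
#'   \item PF sensitivity extension: fracture-chapter "other fracture"
#'     diagnoses (800--829 wildcards).
#'   \item SCC high specificity: 336.9 unspecified disease of spinal cord.
#'   \item SCC sensitivity extension: spondylosis with myelopathy (721.1,
#'     721.41, 721.91) and intervertebral disc disorder with myelopathy
#'     (722.7X).
#'   \item RAD high specificity: 2D/3D external-beam delivery (ICD-9-PX
#'     92.22--92.27 and HCPCS 774xx simple/intermediate/complex delivery)
#'     and radioisotope therapy (92.28/92.29, A9600 strontium-89, A9605
#'     samarium-153).
#'   \item RAD sensitivity extension: IMRT delivery (77418) and stereotactic
#'     radiosurgery (77371--77373, ICD-9-PX 92.3X).
#'   \item BS: internal fixation and fracture-repair procedures (78.5X,
#'     79.3X) plus vertebroplasty/kyphoplasty (22520--22525). Only one BS
#'     list exists; both tiers select it.
#'   \item TRAUMA: transport-accident E-codes (E800--E848) and falls
#'     (E880--E884, E887, E888).
#'   \item SAME_LEVEL_FALL: falls on the same level (E885.X, E886.X).
#'   \item RAD_CONTEXT: bone metastasis (198.5) and bone pain (733.90) for
#'     the optional radiation concurrency filter.
#' }
#' The complete operational lists used on the original restricted data are
#' not public; this default is the documented, user-extensible approximation
#' built from codes the study text names.
#'
#' @return An `"sre_codebook"` object.
#' @export
default_codebook <- function() {
  path <- system.file("extdata", "default_codebook.csv", package = "skelevent")
  if (!nzchar(path)) stop("default codebook not found in installed package")
  load_codebook(path)
}

#' Match a normalized code against a codebook
#'
#' Returns every entry whose pattern matches the code exactly, or by prefix
#' for wildcard patterns, within the same coding system. Order is
#' deterministic: by subtype, then tier.
#'
#' @param cb An `"sre_codebook"`.
#' @param code A single normalized code string.
#' @param system Coding system of the code.
#' @return data.frame with columns `sre_type, tier, role` (zero rows if
#'   nothing matches).
#' @export
match_code <- function(cb, code, system) {
  stopifnot(length(code) == 1)
  system <- match.arg(system, CODE_SYSTEMS)
  hit <- cb$system == system &
    ((!cb$wildcard & cb$prefix == code) |
     (cb$wildcard & startsWith(code, cb$prefix)))
  out <- cb[hit, c("sre_type", "tier", "role")]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

# Vectorized matcher used by the pipeline: returns the claim-row index for
# every (claim, codebook-entry) match as a data.frame alongside the entry's
# sre_type/tier/role. Loops over codebook entries (small) rather than claims.
match_claims <- function(cb, claims) {
  pieces <- lapply(seq_len(nrow(cb)), function(k) {
    sel <- claims$system == cb$system[k] &
      (if (cb$wildcard[k]) startsWith(claims$code, cb$prefix[k])
       else claims$code == cb$prefix[k])
    idx <- which(sel)
    if (!length(idx)) return(NULL)
    data.frame(claim_row = idx, sre_type = cb$sre_type[k], tier = cb$tier[k],
               role = cb$role[k], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(claim_row = integer(), sre_type = character(),
                      tier = character(), role = character())
  }
  out
}

#' Compose a named SRE case definition
#'
#' An SRE definition selects, per subtype, which code tiers count as events,
#' plus option flags for literature variants. Two definitions are built in:
#' \describe{
#'   \item{`"base_case"`}{PF uses both tiers (high sensitivity); SCC and RAD
#'     use the high-specificity tier only; BS uses its single list.}
#'   \item{`"alternative"`}{PF uses the high-specificity tier only; SCC and
#'     RAD use both tiers; BS unchanged.}
#' }
#'
#' @param name `"base_case"`, `"alternative"`, or a name registered via
#'   `tier_selection`.
#' @param tier_selection Optional named list mapping each subtype to a
#'   character vector of tiers, to define a custom selection; BS is always
#'   forced to both tiers (it has a single list).
#' @param same_day_hierarchy If `TRUE`, treatment events (RAD/BS) on a day
#'   that also carries a kept clinical event (PF/SCC) are suppressed.
#'   Default `FALSE`.
#' @param rad_concurrency_filter If `TRUE`, a RAD event is kept only when a
#'   same-day claim carries a bone-metastasis/PF/SCC/bone-pain diagnosis.
#'   Default `FALSE`.
#' @param bs_trauma_lookback If `TRUE`, BS events are subject to the same
#'   trauma lookback rule as "other fracture" events. Default `FALSE`.
#' @return A list of class `"sre_definition"` with elements `name`, `tiers`
#'   and `options`.
#' @export
sre_definition <- function(name = c("base_case", "alternative"),
                           tier_selection = NULL,
                           same_day_hierarchy = FALSE,
                           rad_concurrency_filter = FALSE,
                           bs_trauma_lookback = FALSE) {
  both <- CODE_TIERS
  spec <- "SPECIFICITY"
  if (is.null(tier_selection)) {
    registered <- list(
      base_case  = list(PF = both, SCC = spec, RAD = spec, BS = both),
      alternative = list(PF = spec, SCC = both, RAD = both, BS = both)
    )
    if (length(name) > 1) name <- name[1]
    if (!name %in% names(registered)) {
      stop("unknown SRE definition '", name, "'; registered: ",
           paste(names(registered), collapse = ", "),
           " (or supply tier_selection)", call. = FALSE)
    }
    tiers <- registered[[name]]
  } else {
    if (length(name) > 1) name <- "custom"
    stopifnot(setequal(names(tier_selection), SRE_TYPES))
    tiers <- lapply(tier_selection[SRE_TYPES], function(x) {
      x <- match.arg(x, CODE_TIERS, several.ok = TRUE); x
    })
    tiers$BS <- both  # single BS list: both named definitions share it
  }
  structure(list(name = name, tiers = tiers,
                 options = list(same_day_hierarchy = isTRUE(same_day_hierarchy),
                                rad_concurrency_filter = isTRUE(rad_concurrency_filter),
                                bs_trauma_lookback = isTRUE(bs_trauma_lookback))),
            class = "sre_definition")
}

#' @export
print.sre_definition <- function(x, ...) {
  cat("SRE case definition:", x$name, "\n")
  for (t in SRE_TYPES) {
    cat(sprintf("  %-4s tiers: %s\n", t, paste(x$tiers[[t]], collapse = " + ")))
  }
  on <- names(Filter(isTRUE, x$options))
  cat("  options on:", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Codes selected by a definition for one subtype
#'
#' @param cb An `"sre_codebook"`.
#' @param definition An `"sre_definition"`.
#' @param sre_type Subtype, one of PF/SCC/RAD/BS.
#' @return The codebook rows (EVENT role) selected for that subtype.
#' @export
selected_entries <- function(cb, definition, sre_type) {
  sre_type <- match.arg(sre_type, SRE_TYPES)
  cb[cb$role == "EVENT" & cb$sre_type == sre_type &
       cb$tier %in% definition$tiers[[sre_type]], , drop = FALSE]
}
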