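# Tautomer pair input: the simple name/smiles1/smiles2/logK TSV dialect and
# DataWarrior-style exports (SMILES columns auto-detected, identifiers from
# row numbers), the database filter rules, and log K -> free energy.

#' Convert a base-10 tautomer equilibrium constant to a free energy
#'
#' Databases deposit log10 K; the tautomeric free energy difference is
#' dG = -RT ln K = -RT ln(10) * logK.  A `base` argument is provided for
#' sources that deposit natural-log ratios.
#'
#' @param logK numeric, log equilibrium constant (base 10 by default).
#' @param T temperature in K.
#' @param base logarithm base of the deposited value.
#' @return free energy in kcal/mol.
#' @export
logk_to_free_energy <- function(logK, T = 298.15, base = 10) {
  if (any(!is.finite(logK))) stopf("logK must be finite")
  stopifnot(T > 0, base > 0)
  -CONST$R_kcal * T * log(base) * logK
}

#' Construct a tautomer pair
#'
#' If exactly one of the two tautomers carries a cis/trans stereo bond, the
#' pair is stored with that tautomer first (initial coordinates must come
#' from the topology with the stereo bond present) and the sign of logK is
#' flipped accordingly; `direction_flipped` records this.
#'
#' @param name pair identifier (e.g. `tp_<row>`).
#' @param t1,t2 `taut_molecule` objects.
#' @param logK base-10 log equilibrium constant (t1 -> t2).
#' @param T temperature (K) for the free-energy conversion.
#' @return object of class `tautomer_pair` with fields `dG_exp` (kcal/mol)
#'   and `direction_flipped`.
#' @export
tautomer_pair <- function(name, t1, t2, logK, T = 298.15) {
  stopifnot(inherits(t1, "taut_molecule"), inherits(t2, "taut_molecule"))
  flipped <- FALSE
  if (!any(t1$bonds$stereo) && any(t2$bonds$stereo)) {
    tmp <- t1; t1 <- t2; t2 <- tmp
    logK <- -logK
    flipped <- TRUE
  }
  structure(list(
    name = name, t1 = t1, t2 = t2,
    logK = logK,
    dG_exp = if (is.finite(logK)) logk_to_free_energy(logK, T) else NA_real_,
    T = T,
    direction_flipped = flipped
  ), class = "tautomer_pair")
}

#' @export
print.tautomer_pair <- function(x, ...) {
  cat(sprintf("<tautomer_pair> %s: %s <-> %s  logK=%.3g dG_exp=%.3f kcal/mol%s\n",
              x$name, x$t1$smiles, x$t2$smiles, x$logK, x$dG_exp,
              if (x$direction_flipped) " (direction flipped)" else ""))
  invisible(x)
}

#' Filter rule configuration for tautomer databases
#'
#' Each rule can be switched off.  Defaults reproduce the aqueous,
#' |logK| <= 10, neutral, iodine-free, single proton + double bond shift
#' selection; the CHNO element whitelist and the stereo-bond-change
#' exclusion are off by default (they define narrower subsets used for
#' machine-learned potentials and for alchemical runs respectively).
#'
#' @param aqueous_only keep only aqueous measurements (needs a solvent
#'   column in the table; tables without one are taken as aqueous).
#' @param logk_range keep |logK| <= 10 and reject missing logK.
#' @param no_charged reject any nonzero formal charge.
#' @param no_iodine reject pairs containing iodine.
#' @param single_shift require a unique single-proton shift with a double
#'   bond rearrangement between the tautomers.
#' @param element_whitelist optional character vector (e.g.
#'   `c("C","H","N","O")`); NULL disables.
#' @param exclude_stereobond_change reject pairs where a stereo double bond
#'   changes position between the tautomers.
#' @param blocklist optional character vector of pair names to drop (known
#'   bad database rows).
#' @return list of class `taut_filter_rules`.
#' @export
filter_rules <- function(aqueous_only = TRUE, logk_range = TRUE,
                         no_charged = TRUE, no_iodine = TRUE,
                         single_shift = TRUE, element_whitelist = NULL,
                         exclude_stereobond_change = FALSE,
                         blocklist = NULL) {
  structure(list(aqueous_only = aqueous_only, logk_range = logk_range,
                 no_charged = no_charged, no_iodine = no_iodine,
                 single_shift = single_shift,
                 element_whitelist = element_whitelist,
                 exclude_stereobond_change = exclude_stereobond_change,
                 blocklist = blocklist),
            class = "taut_filter_rules")
}

# guess which columns of a table hold SMILES / logK / solvent
.detect_columns <- function(tab) {
  nm <- names(tab)
  looks_smiles <- function(v) {
    v <- as.character(v)
    ok <- grepl("^[A-Za-z0-9@+\\-\\[\\]()=#/\\\\%.]+$", v) &
      grepl("[cCnNoOsS]", v) & nchar(v) >= 2
    mean(ok, na.rm = TRUE) > 0.8
  }
  smi_named <- grep("smiles", nm, ignore.case = TRUE, value = TRUE)
  smi <- if (length(smi_named) >= 2) smi_named[1:2] else
    nm[vapply(tab, looks_smiles, logical(1))][1:2]
  if (anyNA(smi)) stopf("could not detect two SMILES columns")
  logk_named <- grep("log", nm, ignore.case = TRUE, value = TRUE)
  logk <- if (length(logk_named) >= 1) logk_named[1] else NA_character_
  solv_named <- grep("solv|medium|phase", nm, ignore.case = TRUE, value = TRUE)
  solv <- if (length(solv_named) >= 1) solv_named[1] else NA_character_
  list(smiles = smi, logk = logk, solvent = solv)
}

#' Read a tautomer pair table
#'
#' Accepts the simple dialect (`name`, `smiles1`, `smiles2`, `logK`; header
#' required) or a DataWarrior-style tab-separated export in which the two
#' SMILES columns, the logK column and an optional solvent column are
#' auto-detected; in that case pairs are named `tp_<row>` after their row
#' number in the file.
#'
#' @param path TSV file path.
#' @return data.frame with columns `name`, `smiles1`, `smiles2`, `logK`,
#'   `solvent` (NA when absent).
#' @export
read_pair_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  nm <- tolower(names(tab))
  if (all(c("name", "smiles1", "smiles2", "logk") %in% nm)) {
    names(tab) <- nm
    out <- data.frame(name = as.character(tab$name),
                      smiles1 = tab$smiles1, smiles2 = tab$smiles2,
                      logK = suppressWarnings(as.numeric(tab$logk)),
                      solvent = NA_character_,
                      stringsAsFactors = FALSE)
  } else {
    cols <- .detect_columns(tab)
    out <- data.frame(
      name = paste0("tp_", seq_len(nrow(tab))),
      smiles1 = as.character(tab[[cols$smiles[1]]]),
      smiles2 = as.character(tab[[cols$smiles[2]]]),
      logK = if (is.na(cols$logk)) NA_real_ else
        suppressWarnings(as.numeric(as.character(tab[[cols$logk]]))),
      solvent = if (is.na(cols$solvent)) NA_character_ else
        as.character(tab[[cols$solvent]]),
      stringsAsFactors = FALSE)
  }
  out
}

#' Parse a pair table and apply the database filter rules
#'
#' Rules are applied in a fixed order and each pair is attributed to the
#' first rule it fails, so the per-rule rejection counts plus the retained
#' and unparsable counts always sum to the number of input rows.
#'
#' @param table data.frame from [read_pair_table()] (or a file path).
#' @param rules a [filter_rules()] object.
#' @param T temperature (K) for the logK -> free energy conversion.
#' @return list with `pairs` (list of `tautomer_pair`) and `report`
#'   (per-rule counts and per-row disposition data.frame).
#' @export
parse_and_filter_pairs <- function(table, rules = filter_rules(),
                                   T = 298.15) {
  if (is.character(table)) table <- read_pair_table(table)
  stopifnot(inherits(rules, "taut_filter_rules"))
  counts <- c(unparsable = 0L, not_aqueous = 0L, logk_out_of_range = 0L,
              charged = 0L, iodine = 0L, not_single_shift = 0L,
              element_whitelist = 0L, stereobond_change = 0L,
              blocklisted = 0L, retained = 0L)
  disposition <- character(nrow(table))
  pairs <- list()
  for (r in seq_len(nrow(table))) {
    row <- table[r, ]
    verdict <- NULL
    if (rules$aqueous_only && !is.na(row$solvent) &&
        !grepl("water|aqueous|h2o", row$solvent, ignore.case = TRUE)) {
      verdict <- "not_aqueous"
    }
    if (is.null(verdict) && rules$logk_range &&
        (is.na(row$logK) || abs(row$logK) > 10)) {
      verdict <- "logk_out_of_range"
    }
    pair <- NULL
    if (is.null(verdict)) {
      pair <- tryCatch({
        t1 <- smiles_to_molecule(row$smiles1)
        t2 <- smiles_to_molecule(row$smiles2)
        tautomer_pair(row$name, t1, t2,
                      if (is.na(row$logK)) 0 else row$logK, T = T)
      }, error = function(e) NULL)
      if (is.null(pair)) verdict <- "unparsable"
    }
    if (is.null(verdict) && rules$no_charged &&
        (any(pair$t1$charges != 0L) || any(pair$t2$charges != 0L))) {
      verdict <- "charged"
    }
    if (is.null(verdict) && rules$no_iodine &&
        ("I" %in% pair$t1$elements || "I" %in% pair$t2$elements)) {
      verdict <- "iodine"
    }
    if (is.null(verdict) && rules$single_shift) {
      shift <- tryCatch(find_proton_shift(pair), error = function(e) NULL)
      if (is.null(shift)) verdict <- "not_single_shift"
    }
    if (is.null(verdict) && !is.null(rules$element_whitelist) &&
        !all(c(pair$t1$elements, pair$t2$elements) %in%
             rules$element_whitelist)) {
      verdict <- "element_whitelist"
    }
    if (is.null(verdict) && rules$exclude_stereobond_change &&
        detect_stereobond_change(pair)) {
      verdict <- "stereobond_change"
    }
    if (is.null(verdict) && !is.null(rules$blocklist) &&
        row$name %in% rules$blocklist) {
      verdict <- "blocklisted"
    }
    if (is.null(verdict)) {
      verdict <- "retained"
      pairs[[length(pairs) + 1L]] <- pair
    }
    counts[verdict] <- counts[verdict] + 1L
    disposition[r] <- verdict
  }
  report <- list(counts = counts,
                 disposition = data.frame(name = table$name,
                                          disposition = disposition,
                                          stringsAsFactors = FALSE),
                 n_input = nrow(table))
  list(pairs = pairs, report = report)
}

#' Write a filter report as JSON
#'
#' @param report the `report` element returned by
#'   [parse_and_filter_pairs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(
    list(n_input = report$n_input, counts = as.list(report$counts),
         disposition = report$disposition),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
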