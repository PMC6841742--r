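#' Default drug action simplification table
#'
#' Maps raw target action types onto the three simplified effects:
#' "positive" for actions that increase target activity (agonists,
#' activators, inducers, potentiators), "negative" for actions that
#' decrease it (antagonists, inhibitors, blockers, suppressors), and
#' "other" for the rest (modifiers, ligands, binders, unknown). The table
#' is user-overridable; lookup is case-insensitive.
#'
#' @return Named character vector, lower-cased action -> simplified effect.
#' @export
default_action_map <- function() {
  c(agonist = "positive", activator = "positive", inducer = "positive",
    potentiator = "positive",
    antagonist = "negative", inhibitor = "negative", blocker = "negative",
    suppressor = "negative",
    modifier = "other", ligand = "other", binder = "other",
    unknown = "other")
}

#' Simplify raw drug action types
#'
#' @param action_raw Character vector of raw action labels.
#' @param mapping Named character vector (lower-cased action ->
#'   `positive`/`negative`/`other`), default [default_action_map()].
#' @param unknown Policy for actions absent from the mapping: `"error"`
#'   (default) or `"other"` (mapped to "other" with one warning).
#' @return Character vector of simplified effects.
#' @export
simplify_action <- function(action_raw, mapping = default_action_map(),
                            unknown = c("error", "other")) {
  unknown <- match.arg(unknown)
  bad_val <- setdiff(unique(mapping), c("positive", "negative", "other"))
  if (length(bad_val)) {
    stop("mapping values must be positive/negative/other, got: ",
         paste(bad_val, collapse = ", "), call. = FALSE)
  }
  key <- tolower(action_raw)
  out <- unname(mapping[key])
  if (anyNA(out)) {
    missing <- sort_c(unique(action_raw[is.na(out)]))
    if (unknown == "error") {
      stop("unknown action type(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    warning("unknown action type(s) mapped to 'other': ",
            paste(missing, collapse = ", "), call. = FALSE)
    out[is.na(out)] <- "other"
  }
  out
}

#' Parse drug and drug-target tables
#'
#' The drug table (TSV: `drug_id`, `name`, `indicated`, `contraindicated`,
#' `adverse_inducing`; disease lists ';'-joined) records each drug's
#' disease relations. The companion target table (TSV: `drug_id`, `gene`,
#' `action_raw`, `organism`) records typed target actions; only targets
#' whose organism is "Human"/"Homo sapiens" (case-insensitive) count as
#' human.
#'
#' @param drug_path Path to the drug TSV.
#' @param target_path Path to the target TSV.
#' @return Object of class `drug_table`: list with `drugs` (data.frame,
#'   disease relations as list-columns) and `targets` (data.frame with a
#'   logical `human` column).
#' @export
parse_drug_tables <- function(drug_path, target_path) {
  drugs <- read_evidence_tsv(drug_path,
                             c("drug_id", "name", "indicated",
                               "contraindicated", "adverse_inducing"),
                             "drug table")
  if (anyDuplicated(drugs$drug_id)) {
    stop("drug table: duplicate drug_id: ",
         paste(unique(drugs$drug_id[duplicated(drugs$drug_id)]),
               collapse = ", "), call. = FALSE)
  }
  split_diseases <- function(x) {
    lapply(strsplit(x, ";", fixed = TRUE),
           function(v) v[nzchar(v)])
  }
  drugs$indicated <- split_diseases(drugs$indicated)
  drugs$contraindicated <- split_diseases(drugs$contraindicated)
  drugs$adverse_inducing <- split_diseases(drugs$adverse_inducing)

  targets <- read_evidence_tsv(target_path,
                               c("drug_id", "gene", "action_raw", "organism"),
                               "drug target table")
  orphan <- setdiff(unique(targets$drug_id), drugs$drug_id)
  if (length(orphan)) {
    stop("drug target table: drug_id(s) absent from the drug table: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  targets$human <- tolower(targets$organism) %in% c("human", "homo sapiens")
  structure(list(drugs = drugs, targets = targets), class = "drug_table")
}

#' @export
print.drug_table <- function(x, ...) {
  cat(sprintf("drug table: %d drugs, %d target actions (%d human)\n",
              nrow(x$drugs), nrow(x$targets), sum(x$targets$human)))
  invisible(x)
}

new_drug_group <- function(disease, polarity, drugs) {
  structure(list(disease = disease, polarity = polarity,
                 drugs = sort_c(unique(drugs))),
            class = "drug_group")
}

#' @export
print.drug_group <- function(x, ...) {
  cat(sprintf("drug group: %d drugs %s for %s\n",
              length(x$drugs), x$polarity, x$disease))
  invisible(x)
}

#' Build the beneficial and harmful drug groups for one disease
#'
#' Beneficial drugs are those indicated for the disease; harmful drugs are
#' those contraindicated for it or reported to induce/worsen it (the two
#' harmful sources are pooled into one polarity, the source flag staying
#' in the drug table). A drug appearing on both sides is a paradoxical
#' reaction case (e.g. an anti-asthmatic occasionally provoking
#' bronchospasm): such drugs are removed from the harmful group only,
#' because paradoxical reactions are rare, and are reported.
#'
#' @param drug_table A `drug_table`.
#' @param disease Disease label.
#' @return List with `beneficial` and `harmful` (`drug_group` objects) and
#'   `paradoxical` (sorted drug ids removed from the harmful group).
#' @export
build_drug_groups <- function(drug_table, disease) {
  stopifnot(inherits(drug_table, "drug_table"))
  d <- drug_table$drugs
  has <- function(col) vapply(d[[col]], function(v) disease %in% v, logical(1))
  beneficial <- d$drug_id[has("indicated")]
  harmful_pre <- d$drug_id[has("contraindicated") | has("adverse_inducing")]
  paradoxical <- intersect(beneficial, harmful_pre)
  harmful <- setdiff(harmful_pre, paradoxical)
  list(beneficial = new_drug_group(disease, "beneficial", beneficial),
       harmful = new_drug_group(disease, "harmful", harmful),
       paradoxical = sort_c(paradoxical))
}

#' Human target genes of a drug group
#'
#' Unions the human targets of the group's member drugs; each gene carries
#' the contributing (drug, simplified effect) pairs. Non-human targets are
#' never emitted.
#'
#' @param group A `drug_group`.
#' @param drug_table A `drug_table` containing the group's drugs.
#' @param mapping,unknown Passed to [simplify_action()].
#' @return data.frame with columns `gene`, `drug_id`, `effect`, one row per
#'   distinct (gene, drug, effect) triple, sorted.
#' @export
group_target_genes <- function(group, drug_table,
                               mapping = default_action_map(),
                               unknown = c("error", "other")) {
  stopifnot(inherits(group, "drug_group"), inherits(drug_table, "drug_table"))
  missing <- setdiff(group$drugs, drug_table$drugs$drug_id)
  if (length(missing)) {
    stop("group drug(s) absent from the drug table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tg <- drug_table$targets
  tg <- tg[tg$human & tg$drug_id %in% group$drugs, , drop = FALSE]
  if (!nrow(tg)) {
    return(data.frame(gene = character(0), drug_id = character(0),
                      effect = character(0), stringsAsFactors = FALSE))
  }
  tg$effect <- simplify_action(tg$action_raw, mapping, unknown)
  out <- unique(tg[, c("gene", "drug_id", "effect")])
  out <- out[order_c(out$gene, out$drug_id, out$effect), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drugs beneficial for one disease and harmful for the other
#'
#' The cross-disease overlap at the heart of the adverse-reaction
#' hypothesis: drugs that treat disease A while being contraindicated for
#' or worsening disease B.
#'
#' @param beneficial_A `drug_group` (beneficial, disease A).
#' @param harmful_B `drug_group` (harmful, disease B).
#' @return Sorted character vector of drug ids.
#' @export
cross_disease_harm_overlap <- function(beneficial_A, harmful_B) {
  stopifnot(inherits(beneficial_A, "drug_group"),
            inherits(harmful_B, "drug_group"))
  sort_c(intersect(beneficial_A$drugs, harmful_B$drugs))
}
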