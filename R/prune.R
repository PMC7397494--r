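# Automatic pruning policy: delete whole short chains, individual
# residues and side chains whose predicted correctness falls below
# median-relative thresholds, then remove isolated residues.
#
# Medians are computed once over the scores of the full input structure
# and frozen for all stages. Thresholds use strict "less than": a score
# exactly at a threshold survives. Each stage has an independent cap of
# max_fraction of its eligible population; within a stage, deletion is
# worst-score-first. Stage 1 stops at the first chain whose deletion would
# exceed the residue cap.

#' Pruning configuration
#'
#' @param chain_max_len Maximum chain length eligible for whole-chain
#'   deletion (default 20 residues).
#' @param chain_factor Chains are deleted when their mean main-chain score
#'   is below `chain_factor` x median main score (default 0.2).
#' @param residue_factor Residue deletion threshold as a fraction of the
#'   median main score (default 0.5).
#' @param side_chain_factor Side-chain truncation threshold as a fraction
#'   of the median side score (default 0.5).
#' @param max_fraction_per_stage Cap on the fraction deleted at each stage
#'   (default 0.2).
#' @return Object of class `prune_config`.
#' @export
prune_config <- function(chain_max_len = 20L, chain_factor = 0.2,
                         residue_factor = 0.5, side_chain_factor = 0.5,
                         max_fraction_per_stage = 0.2) {
  stopifnot(chain_max_len >= 1L,
            chain_factor > 0, chain_factor <= 1,
            residue_factor > 0, residue_factor <= 1,
            side_chain_factor > 0, side_chain_factor <= 1,
            max_fraction_per_stage > 0, max_fraction_per_stage <= 1)
  structure(list(chain_max_len = as.integer(chain_max_len),
                 chain_factor = chain_factor,
                 residue_factor = residue_factor,
                 side_chain_factor = side_chain_factor,
                 max_fraction_per_stage = max_fraction_per_stage),
            class = "prune_config")
}

residue_key <- function(df) paste(df$chain, df$seq, df$ins, sep = "|")

#' Is a residue isolated?
#'
#' A residue is isolated when neither the preceding nor the following
#' residue of its chain survives with a peptide-bond-range C-N distance
#' (< 2 A). Chain breaks therefore count as isolation boundaries.
#'
#' @param model A `structure_model` (the surviving model).
#' @param chain,seq,ins Residue key.
#' @return TRUE if the residue has no bonded surviving neighbour.
#' @export
is_isolated <- function(model, chain, seq, ins = "") {
  rt <- residue_table(model)
  i <- which(rt$chain == chain & rt$seq == seq & rt$ins == ins)
  if (!length(i)) stop("is_isolated: residue not found")
  bonded <- peptide_bonded(model)
  prev_ok <- i > 1L && bonded[i - 1L]
  next_ok <- i < nrow(rt) && bonded[i]
  !(prev_ok || next_ok)
}

drop_residues <- function(model, keys) {
  if (!length(keys)) return(model)
  m <- model
  m$atoms <- m$atoms[!(residue_key(m$atoms) %in% keys), , drop = FALSE]
  m
}

drop_side_chains <- function(model, keys) {
  if (!length(keys)) return(model)
  m <- model
  kill <- residue_key(m$atoms) %in% keys & is_side_chain_atom(m$atoms$name)
  m$atoms <- m$atoms[!kill, , drop = FALSE]
  m
}

#' Prune a model using predicted correctness scores
#'
#' Four stages, with medians frozen from the input scores:
#' 1. chains of at most `chain_max_len` residues whose mean main-chain
#'    score is below `chain_factor` x median are deleted worst-mean-first,
#'    subject to the residue cap;
#' 2. remaining residues with main score below `residue_factor` x median
#'    are deleted worst-first up to the cap;
#' 3. side chains (atoms beyond CB) with side score below
#'    `side_chain_factor` x median side score are truncated to CB,
#'    worst-first up to the side-chain cap;
#' 4. isolated residues (no surviving peptide-bonded neighbour) are
#'    removed.
#'
#' @param model A `structure_model`.
#' @param scores Data frame with columns `chain`, `seq`, `ins`,
#'   `main_score` and `side_score` (NA for residues without side chains);
#'   every model residue must have a main score.
#' @param config A `prune_config`.
#' @return List with `model` (the pruned `structure_model`) and `report`
#'   (class `prune_report`: deleted chains/residues/side
#'   chains/isolated, the medians and the thresholds used).
#' @export
prune <- function(model, scores, config = prune_config()) {
  rt <- residue_table(model)
  rt$key <- residue_key(rt)
  scores$key <- residue_key(scores)
  mi <- match(rt$key, scores$key)
  if (any(is.na(mi)) || any(is.na(scores$main_score[mi])))
    stop("prune: missing main score for model residue(s)")
  main <- scores$main_score[mi]
  side <- scores$side_score[mi]
  side_present <- has_side_chain(model)
  if (any(side_present & is.na(side)))
    stop("prune: missing side score for residue(s) with side chains")

  med_main <- stats::median(main)
  med_side <- if (any(side_present)) stats::median(side[side_present]) else NA_real_
  thr_chain <- config$chain_factor * med_main
  thr_res <- config$residue_factor * med_main
  thr_side <- config$side_chain_factor * med_side

  n_res <- nrow(rt)
  cap_res <- floor(config$max_fraction_per_stage * n_res)
  cap_side <- floor(config$max_fraction_per_stage * sum(side_present))

  # stage 1: whole chains, worst mean first, stop when cap would be hit
  chain_ids <- unique(rt$chain)
  chain_stats <- data.frame(
    chain = chain_ids,
    len = vapply(chain_ids, function(ch) sum(rt$chain == ch), integer(1L)),
    mean_main = vapply(chain_ids, function(ch) mean(main[rt$chain == ch]),
                       numeric(1L)))
  elig <- chain_stats[chain_stats$len <= config$chain_max_len &
                        chain_stats$mean_main < thr_chain, , drop = FALSE]
  elig <- elig[order(elig$mean_main), , drop = FALSE]
  deleted_chains <- character(0)
  used <- 0L
  for (k in seq_len(nrow(elig))) {
    if (used + elig$len[k] > cap_res) break
    deleted_chains <- c(deleted_chains, elig$chain[k])
    used <- used + elig$len[k]
  }
  gone <- rt$chain %in% deleted_chains

  # stage 2: individual residues, worst first up to the cap
  cand <- which(!gone & main < thr_res)
  cand <- cand[order(main[cand])]
  if (length(cand) > cap_res) cand <- cand[seq_len(cap_res)]
  deleted_residues <- rt$key[cand]
  gone[cand] <- TRUE

  # stage 3: side chains, worst first up to the side-chain cap
  cand_s <- which(!gone & side_present & !is.na(side) & side < thr_side)
  cand_s <- cand_s[order(side[cand_s])]
  if (length(cand_s) > cap_side) cand_s <- cand_s[seq_len(cap_side)]
  deleted_side <- rt$key[cand_s]

  pruned <- drop_residues(model, c(rt$key[rt$chain %in% deleted_chains],
                                   deleted_residues))
  pruned <- drop_side_chains(pruned, deleted_side)

  # stage 4: isolated residues (cascade-safe loop; converges immediately
  # in practice because removing an isolated residue frees no neighbours)
  deleted_isolated <- character(0)
  repeat {
    if (!nrow(pruned$atoms)) break
    prt <- residue_table(pruned)
    bonded <- peptide_bonded(pruned)
    n <- nrow(prt)
    iso <- vapply(seq_len(n), function(i) {
      prev_ok <- i > 1L && bonded[i - 1L]
      next_ok <- i < n && bonded[i]
      !(prev_ok || next_ok)
    }, logical(1L))
    if (!any(iso)) break
    keys <- residue_key(prt)[iso]
    deleted_isolated <- c(deleted_isolated, keys)
    pruned <- drop_residues(pruned, keys)
  }

  report <- structure(list(
    deleted_chains = deleted_chains,
    deleted_residues = deleted_residues,
    deleted_side_chains = deleted_side,
    deleted_isolated = deleted_isolated,
    medians = list(main = med_main, side = med_side),
    thresholds = list(chain = thr_chain, residue = thr_res, side = thr_side),
    caps = list(residues = cap_res, side_chains = cap_side)),
    class = "prune_report")
  list(model = pruned, report = report)
}

#' @export
print.prune_report <- function(x, ...) {
  cat("prune_report:", length(x$deleted_chains), "chain(s),",
      length(x$deleted_residues), "residue(s),",
      length(x$deleted_side_chains), "side chain(s),",
      length(x$deleted_isolated), "isolated residue(s) deleted\n")
  invisible(x)
}
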