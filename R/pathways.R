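# The three proposed ammonia-oxidation pathways of marine AOA, their
# LP-derived combined reactions and theoretical ATP/NADH yields.

# Species held at steady state inside the pathway (must balance to zero
# in the combined reaction) versus species exchanged with the
# surroundings. NAD/NADH sit on the internal side in ATP mode (no NADH
# demand, so the NADH branch is silent) and on the boundary side in
# NADH mode.
.pathway_internal <- c("nh3", "nh2oh", "no", "q", "qh2",
                       "pcym", "pcyme", "pcy", "pcye", "h_p")
.pathway_boundary <- c("nh4", "o2", "h2o", "hno2", "n2o",
                       "adp", "pi", "atp", "h_c")

#' Load one of the three ammonia-oxidation pathway definitions
#'
#' Pathway 1: quinol-dependent ammonia monooxygenase (AMO) plus
#' hydroxylamine oxidoreductase (HAO). Pathway 2: NO-shuttle AMO
#' (`AMO_NO`) plus HAO. Pathway 3: quinol-dependent AMO plus the
#' proposed CuP460 enzyme with NO cycling. All three share the
#' transporter, quinone reductase, nitrite reductase (reconstructed;
#' see the shipped fixture files), the abiotic N2O reaction, the
#' bc1/aa3 chain, ATP synthase and the NADH branch.
#'
#' @param id Pathway number: 1, 2 or 3.
#' @return A `pathway_def`: list with `id`, `reactions`,
#'   `internal_species`, `boundary_species`.
#' @export
get_pathway <- function(id) {
  if (!id %in% 1:3) abort(sprintf("unknown pathway id '%s' (must be 1, 2 or 3)", id))
  path <- system.file("extdata", "pathways", sprintf("pathway%d.tsv", id),
                      package = "aoaflux", mustWork = TRUE)
  model <- read_table_model(path)
  structure(
    list(id = as.integer(id), reactions = model$reactions,
         internal_species = .pathway_internal,
         boundary_species = c(.pathway_boundary, "nad", "nadh")),
    class = "pathway_def"
  )
}

#' @export
print.pathway_def <- function(x, ...) {
  cat(sprintf("<pathway_def> ammonia-oxidation pathway %d (%d reactions)\n",
              x$id, length(x$reactions)))
  for (r in x$reactions) cat(sprintf("  %-10s %s\n", r$id, render_equation(r)))
  invisible(x)
}

#' Theoretical ATP/NADH yield of an ammonia-oxidation pathway
#'
#' Combines the pathway's reactions by linear programming: nonnegative
#' fluxes, ammonium consumption fixed at 1, every internal species
#' balanced to zero, boundary species free; the production of ATP
#' (or of NADH, then secondarily ATP) is maximized. The optimal fluxes
#' are lumped by [net_reaction()] into the pathway's overall reaction.
#'
#' @param pathway A `pathway_def` from [get_pathway()].
#' @param maximize `"atp"` or `"nadh"` - which product to maximize.
#'   In NADH mode NAD/NADH are boundary species and ATP production is
#'   maximized lexicographically after NADH.
#' @return A `yield_result`: list with `atp_per_nh4`, `nadh_per_nh4`,
#'   `net` (the combined `rxn`), `fluxes`, `pathway`.
#' @export
theoretical_yield <- function(pathway, maximize = c("atp", "nadh")) {
  maximize <- match.arg(maximize)
  rxns <- pathway$reactions
  ids <- names(rxns)
  internal <- pathway$internal_species
  if (maximize == "atp") internal <- c(internal, "nad", "nadh")

  all_sp <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  S_all <- matrix(0, length(all_sp), length(ids), dimnames = list(all_sp, ids))
  for (r in rxns) S_all[names(r$stoich), r$id] <- r$stoich
  internal <- intersect(internal, all_sp)
  if (!"nh4" %in% all_sp)
    abort(sprintf("pathway %d is infeasible: no reaction consumes ammonium", pathway$id))

  Aeq <- rbind(S_all[internal, , drop = FALSE], nh4 = S_all["nh4", ])
  beq <- c(rep(0, length(internal)), -1)
  lb <- setNames(rep(0, length(ids)), ids)
  ub <- setNames(rep(1000, length(ids)), ids)

  net_row <- function(sp) if (sp %in% all_sp) S_all[sp, ] else setNames(rep(0, length(ids)), ids)
  obj_atp <- net_row("atp")
  obj_nadh <- net_row("nadh")

  primary <- if (maximize == "atp") obj_atp else obj_nadh
  sol <- lp_solve(primary, Aeq, beq, lb, ub, "max")
  if (sol$status != "optimal") yield_infeasible(pathway, rxns, internal, S_all)
  if (maximize == "nadh") {
    # fix NADH production, then maximize ATP (documented lexicographic order)
    Aeq2 <- rbind(Aeq, nadh_opt = obj_nadh)
    beq2 <- c(beq, sum(obj_nadh * sol$v))
    sol <- lp_solve(obj_atp, Aeq2, beq2, lb, ub, "max")
    if (sol$status != "optimal") yield_infeasible(pathway, rxns, internal, S_all)
  }

  fluxes <- sol$v
  net <- net_reaction(rxns, fluxes, id = sprintf("pathway%d_%s", pathway$id, maximize))
  res <- structure(
    list(pathway_id = pathway$id, mode = maximize,
         atp_per_nh4 = sum(obj_atp * fluxes),
         nadh_per_nh4 = sum(obj_nadh * fluxes),
         net = net, fluxes = fluxes, pathway = pathway),
    class = "yield_result"
  )
  leftover <- intersect(names(net$stoich), internal)
  if (length(leftover))
    abort(sprintf("internal species not eliminated from net reaction: %s",
                  paste(leftover, collapse = ", ")))
  res
}

yield_infeasible <- function(pathway, rxns, internal, S_all) {
  # which internal species cannot be balanced at unit ammonium uptake?
  produced <- rownames(S_all)[apply(S_all > 0, 1, any)]
  consumed <- rownames(S_all)[apply(S_all < 0, 1, any)]
  oneway <- setdiff(union(setdiff(internal, produced), setdiff(internal, consumed)), character(0))
  abort(sprintf(
    "pathway %d is infeasible at unit ammonium uptake%s", pathway$id,
    if (length(oneway))
      sprintf("; internal species produced or consumed only one way: %s",
              paste(sort(oneway), collapse = ", "))
    else ""))
}

#' @export
print.yield_result <- function(x, ...) {
  cat(sprintf("<yield_result> pathway %d, %s mode\n", x$pathway_id, toupper(x$mode)))
  cat(sprintf("  %s\n", render_equation(x$net)))
  cat(sprintf("  ATP/NH4+: %g   NADH/NH4+: %g\n", x$atp_per_nh4, x$nadh_per_nh4))
  invisible(x)
}

#' @export
tidy.yield_result <- function(x, ...) {
  tibble(pathway = x$pathway_id, mode = x$mode,
         species = names(x$net$stoich), coefficient = unname(x$net$stoich))
}

#' @export
glance.yield_result <- function(x, ...) {
  tibble(pathway = x$pathway_id, mode = x$mode,
         atp_per_nh4 = x$atp_per_nh4, nadh_per_nh4 = x$nadh_per_nh4)
}

#' Proton bookkeeping for a pathway yield
#'
#' Sums the outside-proton (`h_p`) production of every reaction except
#' ATP synthase: the protons translocated outward and available to the
#' synthase, which makes one ATP per 4. NADH carries 4
#' proton-equivalents each, so
#' `proton_equivalents = protons_translocated + 4 * NADH yield` is
#' conserved between the ATP and NADH modes of a pathway.
#'
#' @param result A `yield_result`.
#' @return A one-row tibble: `pathway`, `mode`, `protons_translocated`,
#'   `atp_per_nh4`, `nadh_per_nh4`, `proton_equivalents`.
#' @export
proton_ledger <- function(result) {
  fluxes <- result$fluxes
  protons <- sum(vapply(result$pathway$reactions, function(r) {
    if (r$id == "ATP_Synt") return(0)
    coef <- if ("h_p" %in% names(r$stoich)) r$stoich[["h_p"]] else 0
    fluxes[[r$id]] * coef
  }, numeric(1)))
  tibble(
    pathway = result$pathway_id, mode = result$mode,
    protons_translocated = protons,
    atp_per_nh4 = result$atp_per_nh4,
    nadh_per_nh4 = result$nadh_per_nh4,
    proton_equivalents = protons + 4 * result$nadh_per_nh4
  )
}
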