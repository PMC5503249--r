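## Reaction network of the branched Entner-Doudoroff (ED) pathway:
## glucose -> pyruvate via a semi-phosphorylative (spED) branch
## (KDG -> KDPG -> GAP -> ... -> 2-PG) and a non-phosphorylative (npED)
## branch (KDG -> GA + Pyr, GA -> Gly -> 2-PG).  The two branches
## bifurcate at KDG and converge at 2-PG.

#' State metabolites of the branched ED pathway
#'
#' Twelve state metabolites are tracked.  Cofactor pools (ATP/ADP,
#' NADP+/NADPH, ferredoxin) are clamped and never appear as states.
#' The thermolabile intermediates GAP, 1,3-BPG and PEP additionally carry
#' first-order decay reactions parameterized from measured half-lives.
#'
#' @return A data frame with columns `id`, `name`, `carbon` (number of
#'   carbon atoms) and `thermolabile`.
#' @export
ed_metabolites <- function() {
  data.frame(
    id = c("Glc", "DGat", "KDG", "KDPG", "GAP", "BPG",
           "PG3", "PG2", "PEP", "Pyr", "GA", "Gly"),
    name = c("D-glucose", "D-gluconate", "2-keto-3-deoxygluconate",
             "2-keto-3-deoxy-6-phosphogluconate",
             "glyceraldehyde 3-phosphate", "1,3-bisphosphoglycerate",
             "3-phosphoglycerate", "2-phosphoglycerate",
             "phosphoenolpyruvate", "pyruvate", "glyceraldehyde",
             "glycerate"),
    carbon = c(6L, 6L, 6L, 6L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L),
    thermolabile = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                     FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

## internal: canonical state ordering
.ed_state_ids <- function() ed_metabolites()$id

#' Default reaction topology of the branched ED pathway
#'
#' Declarative listing of the 20 reactions (influx, 14 enzymatic steps of
#' which 5 are reversible, 2 sinks, 3 degradation reactions).  Substrates
#' and products are given as `"id"` or `"id:stoich"` separated by `"+"`.
#'
#' @return A data frame consumed by [build_network()].
#' @export
ed_topology <- function() {
  rbind(
    data.frame(id = "v_up",        substrates = "",          products = "Glc",
               reversible = FALSE, rate_law = "influx",      cofactor = "",
               regulators = ""),
    data.frame(id = "v_GDH",       substrates = "Glc",       products = "DGat",
               reversible = FALSE, rate_law = "mm",          cofactor = "NADP",
               regulators = ""),
    data.frame(id = "v_GAD",       substrates = "DGat",      products = "KDG",
               reversible = FALSE, rate_law = "mm",          cofactor = "",
               regulators = ""),
    data.frame(id = "v_KDGK",      substrates = "KDG",       products = "KDPG",
               reversible = FALSE, rate_law = "mm",          cofactor = "ATP",
               regulators = ""),
    data.frame(id = "v_KDPGA_sp",  substrates = "KDPG",      products = "GAP+Pyr",
               reversible = FALSE, rate_law = "mm",          cofactor = "",
               regulators = ""),
    data.frame(id = "v_KDPGA_np",  substrates = "KDG",       products = "GA+Pyr",
               reversible = TRUE,  rate_law = "rev_mm",      cofactor = "",
               regulators = ""),
    data.frame(id = "v_GAPDH",     substrates = "GAP",       products = "BPG",
               reversible = TRUE,  rate_law = "rev_mm",      cofactor = "NADP",
               regulators = ""),
    data.frame(id = "v_GAPN",      substrates = "GAP",       products = "PG3",
               reversible = FALSE, rate_law = "mm",          cofactor = "NADP",
               regulators = ""),
    data.frame(id = "v_PGK",       substrates = "BPG",       products = "PG3",
               reversible = TRUE,  rate_law = "rev_mm_inhibited",
               cofactor = "ADP",   regulators = "PG3"),
    data.frame(id = "v_iPGAM",     substrates = "PG3",       products = "PG2",
               reversible = TRUE,  rate_law = "rev_mm",      cofactor = "",
               regulators = ""),
    data.frame(id = "v_GAOR",      substrates = "GA",        products = "Gly",
               reversible = FALSE, rate_law = "mm",          cofactor = "Fd",
               regulators = ""),
    data.frame(id = "v_GK",        substrates = "Gly",       products = "PG2",
               reversible = FALSE, rate_law = "mm_substrate_inhibition",
               cofactor = "ATP",   regulators = "Gly"),
    data.frame(id = "v_ENO",       substrates = "PG2",       products = "PEP",
               reversible = TRUE,  rate_law = "rev_mm",      cofactor = "",
               regulators = ""),
    data.frame(id = "v_PK",        substrates = "PEP",       products = "Pyr",
               reversible = FALSE, rate_law = "mm",          cofactor = "ADP",
               regulators = ""),
    data.frame(id = "v_PEPS",      substrates = "Pyr",       products = "PEP",
               reversible = FALSE, rate_law = "mm",          cofactor = "ATP",
               regulators = ""),
    data.frame(id = "v_sinkGAP",   substrates = "GAP",       products = "",
               reversible = FALSE, rate_law = "first_order", cofactor = "",
               regulators = ""),
    data.frame(id = "v_sinkPyr",   substrates = "Pyr",       products = "",
               reversible = FALSE, rate_law = "first_order", cofactor = "",
               regulators = ""),
    data.frame(id = "v_degGAP",    substrates = "GAP",       products = "",
               reversible = FALSE, rate_law = "first_order", cofactor = "",
               regulators = ""),
    data.frame(id = "v_degBPG",    substrates = "BPG",       products = "",
               reversible = FALSE, rate_law = "first_order", cofactor = "",
               regulators = ""),
    data.frame(id = "v_degPEP",    substrates = "PEP",       products = "",
               reversible = FALSE, rate_law = "first_order", cofactor = "",
               regulators = "")
  )
}

.parse_side <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) return(setNames(numeric(0), character(0)))
  parts <- strsplit(txt, "+", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  ids <- sub(":.*$", "", parts)
  st <- ifelse(grepl(":", parts), as.numeric(sub("^.*:", "", parts)), 1)
  setNames(st, ids)
}

#' Build and validate the reaction network
#'
#' Parses a declarative topology table into a network object, builds the
#' stoichiometric matrix and checks every reaction for carbon balance
#' (C6 species cleave into two C3 species at both aldolase reactions;
#' sinks and degradation reactions remove whole carbon skeletons from the
#' modelled subsystem and are exempt).
#'
#' @param topology A data frame as returned by [ed_topology()].
#' @return An object of class `ed_network` with the parsed reactions and
#'   the 12 x n stoichiometric matrix.
#' @export
build_network <- function(topology = ed_topology()) {
  met <- ed_metabolites()
  required <- c("id", "substrates", "products", "reversible", "rate_law")
  if (!all(required %in% names(topology)))
    stop("topology table must have columns: ", paste(required, collapse = ", "))
  reactions <- lapply(seq_len(nrow(topology)), function(i) {
    row <- topology[i, ]
    sub <- .parse_side(row$substrates)
    prod <- .parse_side(row$products)
    unknown <- setdiff(c(names(sub), names(prod)), met$id)
    if (length(unknown))
      stop("unknown metabolite id in reaction ", row$id, ": ",
           paste(unknown, collapse = ", "))
    list(id = row$id, substrates = sub, products = prod,
         reversible = isTRUE(row$reversible), rate_law = row$rate_law,
         cofactor = if (nzchar(row$cofactor)) row$cofactor else NA_character_,
         regulators = if (nzchar(row$regulators))
           strsplit(row$regulators, ",")[[1]] else character(0))
  })
  names(reactions) <- topology$id

  S <- matrix(0, nrow = nrow(met), ncol = length(reactions),
              dimnames = list(met$id, names(reactions)))
  carbon <- setNames(met$carbon, met$id)
  for (r in reactions) {
    S[names(r$substrates), r$id] <- S[names(r$substrates), r$id] - r$substrates
    S[names(r$products), r$id] <- S[names(r$products), r$id] + r$products
    exempt <- r$rate_law %in% c("influx", "first_order")
    if (!exempt) {
      cin <- sum(carbon[names(r$substrates)] * r$substrates)
      cout <- sum(carbon[names(r$products)] * r$products)
      if (!isTRUE(all.equal(cin, cout)))
        stop("carbon imbalance in reaction ", r$id, ": ", cin, " vs ", cout)
    }
  }

  structure(list(metabolites = met, reactions = reactions,
                 stoichiometry = S),
            class = "ed_network")
}

#' @export
print.ed_network <- function(x, ...) {
  nrev <- sum(vapply(x$reactions, `[[`, logical(1), "reversible"))
  cat("Branched ED pathway network:", nrow(x$metabolites),
      "metabolites,", length(x$reactions), "reactions (",
      nrev, "reversible, counted per direction:",
      length(x$reactions) + nrev, "velocities)\n")
  invisible(x)
}

#' Directional velocity names of a network
#'
#' Every irreversible reaction contributes one maximal-velocity parameter;
#' every reversible reaction contributes a forward (`_f`, catabolic) and a
#' reverse (`_r`) velocity.  Sinks and degradation reactions are
#' first-order and carry rate constants instead.
#'
#' @param network An `ed_network`.
#' @param include_first_order Also list sink/degradation rate names.
#' @return Character vector of velocity parameter names.
#' @export
velocity_names <- function(network = build_network(),
                           include_first_order = FALSE) {
  out <- character(0)
  for (r in network$reactions) {
    if (r$rate_law == "first_order") {
      if (include_first_order) out <- c(out, r$id)
    } else if (r$reversible) {
      out <- c(out, paste0(r$id, "_f"), paste0(r$id, "_r"))
    } else {
      out <- c(out, r$id)
    }
  }
  out
}
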