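#' Build a combined cortical + cerebellar parcel atlas
#'
#' Constructs the parcel lookup table every other stage keys on: `n_cortical`
#' cortical parcels labelled with one of the seven canonical resting-state
#' networks and a hemisphere, plus `n_cerebellar` cerebellar parcels labelled
#' with a hemisphere-averaged lobule group (or vermis). The default sizes
#' mirror a 400-parcel cortical atlas combined with a 28-region cerebellar
#' lobular atlas (10 lobule groups per hemisphere plus 8 vermal regions).
#'
#' @param n_cortical Number of cortical parcels (default 400; must be even).
#' @param n_cerebellar Number of cerebellar parcels (default 28).
#' @return A data.frame of class `cc_atlas` with columns `parcel_id`, `name`,
#'   `structure` ("cortex"/"cerebellum"), `hemisphere` ("L"/"R"/"vermis"),
#'   `network` (cortex only), `lobule` (cerebellum only).
#' @examples
#' atl <- parcel_atlas()
#' table(atl$structure)
#' @export
parcel_atlas <- function(n_cortical = 400, n_cerebellar = 28) {
  check_scalar_number(n_cortical, "n_cortical", positive = TRUE)
  check_scalar_number(n_cerebellar, "n_cerebellar", positive = TRUE)
  if (n_cortical %% 2 != 0)
    stop_invalid("n_cortical must be even (equal hemispheres)")

  networks <- cc_networks()
  lobules <- cc_lobules()

  per_hemi <- n_cortical / 2
  net_assign <- networks[((seq_len(per_hemi) - 1L) %% 7L) + 1L]
  net_assign <- sort(factor(net_assign, levels = networks))
  ctx <- data.frame(
    structure = "cortex",
    hemisphere = rep(c("L", "R"), each = per_hemi),
    network = as.character(rep(net_assign, 2)),
    lobule = NA_character_,
    stringsAsFactors = FALSE
  )
  idx_in_net <- stats::ave(seq_len(n_cortical), ctx$hemisphere, ctx$network,
                           FUN = seq_along)
  ctx$name <- sprintf("CTX_%sH_%s_%03d", ctx$hemisphere, ctx$network, idx_in_net)

  # Cerebellum: paired (L/R) lobule parcels first, remainder as vermal regions.
  n_pairs <- min(length(lobules), floor(n_cerebellar / 2))
  n_vermis <- n_cerebellar - 2 * n_pairs
  cb_lob <- c(rep(lobules[seq_len(n_pairs)], 2),
              lobules[((seq_len(n_vermis) - 1L) %% length(lobules)) + 1L])
  cb_hemi <- c(rep(c("L", "R"), each = n_pairs), rep("vermis", n_vermis))
  cbm <- data.frame(
    structure = "cerebellum",
    hemisphere = cb_hemi,
    network = NA_character_,
    lobule = cb_lob,
    stringsAsFactors = FALSE
  )
  cbm$name <- ifelse(cbm$hemisphere == "vermis",
                     sprintf("CBM_Vermis_%s", cbm$lobule),
                     sprintf("CBM_%s_%s", cbm$hemisphere, cbm$lobule))

  atlas <- rbind(ctx, cbm)
  atlas$parcel_id <- seq_len(nrow(atlas))
  atlas <- atlas[, c("parcel_id", "name", "structure", "hemisphere",
                     "network", "lobule")]
  class(atlas) <- c("cc_atlas", "data.frame")
  atlas
}

#' Canonical cortical network names
#' @return Character vector of the seven network labels.
#' @export
cc_networks <- function() {
  c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic", "Cont", "Default")
}

#' Cerebellar lobule group names
#' @return Character vector of the ten hemisphere-averaged lobule groups.
#' @export
cc_lobules <- function() {
  c("I_IV", "V", "VI", "CrusI", "CrusII", "VIIb", "VIIIa", "VIIIb", "IX", "X")
}

#' @export
print.cc_atlas <- function(x, ...) {
  cat(sprintf("<cc_atlas> %d parcels (%d cortical, %d cerebellar)\n",
              nrow(x), sum(x$structure == "cortex"),
              sum(x$structure == "cerebellum")))
  invisible(x)
}

cortex_idx <- function(atlas) which(atlas$structure == "cortex")
cerebellum_idx <- function(atlas) which(atlas$structure == "cerebellum")

validate_atlas <- function(atlas) {
  if (!inherits(atlas, "cc_atlas")) stop_invalid("atlas must be a cc_atlas")
  if (anyNA(atlas$network[atlas$structure == "cortex"]))
    stop_invalid("every cortical parcel must carry a network label")
  if (anyNA(atlas$lobule[atlas$structure == "cerebellum"]))
    stop_invalid("every cerebellar parcel must carry a lobule label")
  invisible(atlas)
}
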