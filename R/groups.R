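#' Subpopulation group labels
#'
#' The metapopulation is discretised into four wintering subpopulation groups:
#' three focal groups with individually marked birds (`"W"` Wexford-type,
#' `"Is"` Islay-type, `"LK"` Loch Ken-type) and a pooled `"E"` (Elsewhere)
#' group collecting all remaining wintering sites. The Elsewhere group always
#' comes last; juvenile capture histories exist only for focal groups.
#'
#' @return Character vector of the four group codes, focal groups first.
#' @export
imm_groups <- function() c("W", "Is", "LK", "E")

#' Number of focal groups
#' @return Integer, currently 3.
#' @export
imm_n_focal <- function() 3L

#' Enumerate dispersal flows
#'
#' Movement (dispersal) probabilities are estimated per directed group pair
#' and age class. Adult flows connect every ordered pair of groups; juvenile
#' flows connect focal groups with each other and focal groups with Elsewhere,
#' but never Elsewhere to a focal group (no juvenile capture histories exist
#' for Elsewhere, so those rates are structurally zero).
#'
#' @return A data.frame with columns `age` ("J" or "A"), `from`, `to`
#'   (group codes) and integer indices `from_i`, `to_i`.
#' @export
imm_flows <- function() {
  g <- imm_groups()
  nf <- imm_n_focal()
  juv <- expand.grid(from_i = seq_len(nf), to_i = seq_along(g),
                     KEEP.OUT.ATTRS = FALSE)
  juv <- juv[juv$from_i != juv$to_i, , drop = FALSE]
  ad <- expand.grid(from_i = seq_along(g), to_i = seq_along(g),
                    KEEP.OUT.ATTRS = FALSE)
  ad <- ad[ad$from_i != ad$to_i, , drop = FALSE]
  out <- rbind(
    data.frame(age = "J", from_i = juv$from_i, to_i = juv$to_i),
    data.frame(age = "A", from_i = ad$from_i, to_i = ad$to_i)
  )
  # stable, readable order: by age, then source, then destination
  out <- out[order(out$age, out$from_i, out$to_i), , drop = FALSE]
  out$from <- g[out$from_i]
  out$to <- g[out$to_i]
  rownames(out) <- NULL
  out[, c("age", "from", "to", "from_i", "to_i")]
}

logit <- function(p) log(p) - log1p(-p)
invlogit <- function(x) 1 / (1 + exp(-x))

round_half_up <- function(x) floor(x + 0.5)
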