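#' Sequencing cost model parameters
#'
#' Parameters of the pooled-versus-barcoded cost comparison: a lane produces
#' `reads_per_lane` reads of `read_length` bp at a fixed `lane_cost`; each
#' barcoded library costs `library_cost`; the target region of
#' `target_length` bp must reach `coverage` for the lowest-concentration
#' pool member. Defaults correspond to a MiSeq-style run re-sequencing a
#' 5,000 bp amplicon at 1,000x.
#'
#' @param reads_per_lane reads produced per lane (default 20e6).
#' @param read_length read length in bp (default 150).
#' @param lane_cost fixed cost per lane (default 2000).
#' @param library_cost library preparation cost per barcoded sample
#'   (default 50).
#' @param target_length target region length in bp (default 5000).
#' @param coverage required depth for the lowest-concentration member
#'   (default 1000).
#' @param ratios pool mixing ratios (default `c(1, 2, 5)`).
#' @return List of class `cost_model`.
#' @export
cost_model <- function(reads_per_lane = 20e6, read_length = 150,
                       lane_cost = 2000, library_cost = 50,
                       target_length = 5000, coverage = 1000,
                       ratios = c(1, 2, 5)) {
  stopifnot(reads_per_lane > 0, read_length > 0, lane_cost > 0,
            library_cost >= 0, target_length > 0, coverage > 0,
            all(ratios > 0))
  structure(list(reads_per_lane = reads_per_lane,
                 read_length = read_length, lane_cost = lane_cost,
                 library_cost = library_cost,
                 target_length = target_length, coverage = coverage,
                 ratios = ratios, pool_size = length(ratios)),
            class = "cost_model")
}

#' Cost of the one-barcode-per-individual approach
#'
#' Every individual gets its own library; lanes are added as needed to give
#' each individual `coverage` over the target region.
#'
#' @param i number of individuals.
#' @param model a [cost_model()].
#' @return Total cost.
#' @export
barcoded_cost <- function(i, model = cost_model()) {
  stopifnot(i >= 1)
  reads <- i * model$coverage * model$target_length / model$read_length
  lanes <- lanes_needed(reads, model$reads_per_lane)
  i * model$library_cost + lanes * model$lane_cost
}

# ceiling with a relative tolerance so that an exactly full lane does not
# spill into a new one through floating-point noise
lanes_needed <- function(reads, reads_per_lane) {
  x <- reads / reads_per_lane
  ceiling(x * (1 - 1e-12))
}

#' Cost of the pooled approach
#'
#' Individuals are grouped into pools of `pool_size` sharing one library;
#' within a pool the mixing ratios mean the lowest-concentration member at
#' coverage `c` forces `sum(ratios) / min(ratio)`-fold more sequencing per
#' pool (e.g. 8x the single-individual requirement for 1:2:5). A final
#' partial group, if any, is barcoded individually.
#'
#' @inheritParams barcoded_cost
#' @return Total cost.
#' @export
pooled_cost <- function(i, model = cost_model()) {
  stopifnot(i >= 1)
  pools <- i %/% model$pool_size
  rem <- i %% model$pool_size
  per_ind_reads <- model$coverage * model$target_length / model$read_length
  pool_reads <- sum(model$ratios) / min(model$ratios) * per_ind_reads
  reads <- pools * pool_reads + rem * per_ind_reads
  lanes <- lanes_needed(reads, model$reads_per_lane)
  (pools + rem) * model$library_cost + lanes * model$lane_cost
}

#' Relative saving of pooling over barcoding
#'
#' @inheritParams barcoded_cost
#' @return Percentage saving, rounded to the nearest integer.
#' @examples
#' savings_percent(51)   # 37
#' savings_percent(102)  # 48
#' @export
savings_percent <- function(i, model = cost_model()) {
  round(100 * (1 - pooled_cost(i, model) / barcoded_cost(i, model)))
}

#' Cost curves over a range of cohort sizes
#'
#' @param individuals integer vector of cohort sizes.
#' @param model a [cost_model()].
#' @return Data frame of class `cost_sweep` with per-size barcoded and
#'   pooled totals and the percentage saving.
#' @export
cost_sweep <- function(individuals, model = cost_model()) {
  out <- data.frame(
    individuals = individuals,
    barcoded = vapply(individuals, barcoded_cost, numeric(1),
                      model = model),
    pooled = vapply(individuals, pooled_cost, numeric(1), model = model)
  )
  out$savings_percent <- round(100 * (1 - out$pooled / out$barcoded))
  class(out) <- c("cost_sweep", "data.frame")
  out
}

#' @export
plot.cost_sweep <- function(x, ...) {
  graphics::plot(x$individuals, x$barcoded, type = "s",
                 xlab = "individuals", ylab = "total cost",
                 ylim = range(0, x$barcoded, x$pooled), ...)
  graphics::lines(x$individuals, x$pooled, type = "s", col = "blue")
  graphics::legend("topleft", legend = c("barcoded", "pooled"),
                   col = c("black", "blue"), lty = 1, bty = "n")
  invisible(x)
}
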