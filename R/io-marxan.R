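#' Write a planning problem in the Marxan file convention
#'
#' Emits the four classic tab-separated planning files into `out_dir`:
#' `pu.dat` (`id,cost,status`), `spec.dat` (`id,prop,spf,name`),
#' `puvspr.dat` (`species,pu,amount`, sorted by planning unit then feature),
#' and `bound.dat` (`id1,id2,boundary` with `id1 < id2`, each pair once).
#' Status codes follow the convention: 0 available, 2 locked in, 3 locked out.
#'
#' @param problem A [planning_problem()].
#' @param out_dir Output directory (created if missing).
#' @return The four file paths, invisibly.
#' @export
write_marxan <- function(problem, out_dir) {
  stopifnot(inherits(problem, "planning_problem"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  status_code <- c(available = 0L, locked_in = 2L, locked_out = 3L)

  pu <- data.frame(id = problem$units$id,
                   cost = problem$units$cost,
                   status = status_code[problem$units$status])
  f_pu <- file.path(out_dir, "pu.dat")
  utils::write.table(pu, f_pu, sep = "\t", row.names = FALSE, quote = FALSE)

  sp <- data.frame(id = problem$features$id,
                   prop = problem$features$prop,
                   spf = problem$features$spf,
                   name = problem$features$name)
  f_sp <- file.path(out_dir, "spec.dat")
  utils::write.table(sp, f_sp, sep = "\t", row.names = FALSE, quote = FALSE)

  pv <- problem$amounts[problem$amounts$amount > 0, , drop = FALSE]
  pv <- pv[order(pv$pu, pv$feature), c("feature", "pu", "amount")]
  names(pv) <- c("species", "pu", "amount")
  f_pv <- file.path(out_dir, "puvspr.dat")
  utils::write.table(pv, f_pv, sep = "\t", row.names = FALSE, quote = FALSE)

  bd <- problem$boundaries[order(problem$boundaries$id1, problem$boundaries$id2), ]
  f_bd <- file.path(out_dir, "bound.dat")
  utils::write.table(bd, f_bd, sep = "\t", row.names = FALSE, quote = FALSE)

  invisible(c(f_pu, f_sp, f_pv, f_bd))
}

#' Read Marxan-convention planning files back into tibbles
#'
#' @param out_dir Directory holding `pu.dat`, `spec.dat`, `puvspr.dat`,
#'   `bound.dat`.
#' @return A list of tibbles `pu`, `spec`, `puvspr`, `bound`.
#' @export
read_marxan <- function(out_dir) {
  rd <- function(f) tibble::as_tibble(
    utils::read.table(file.path(out_dir, f), header = TRUE, sep = "\t")
  )
  list(pu = rd("pu.dat"), spec = rd("spec.dat"),
       puvspr = rd("puvspr.dat"), bound = rd("bound.dat"))
}
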