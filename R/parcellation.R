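#' Parcellation label tables
#'
#' A parcellation table maps region indices to names, functional networks and
#' compartment (cortical/subcortical). [default_parcellation()] builds the
#' 116-region table the pipeline assumes by default: 100 cortical regions
#' organised into the seven canonical resting-state networks (50 per
#' hemisphere) plus 16 subcortical regions (8 structures per hemisphere).
#' Region names are synthetic placeholders laid out in the standard
#' hemisphere/network naming style; they carry no anatomical coordinates.
#' [make_parcellation()] builds a generic table of any size for synthetic
#' cohorts.
#'
#' @return a data frame with columns `index`, `name`, `network`,
#'   `compartment`.
#' @export
default_parcellation <- function() {
  networks <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic",
                "Cont", "Default")
  # 50 cortical regions per hemisphere split across the 7 networks
  per_net <- c(Vis = 9, SomMot = 8, DorsAttn = 7, SalVentAttn = 7,
               Limbic = 4, Cont = 7, Default = 8)
  stopifnot(sum(per_net) == 50)
  cortical <- do.call(rbind, lapply(c("LH", "RH"), function(h) {
    do.call(rbind, lapply(networks, function(nw) {
      data.frame(name = sprintf("%s_%s_%d", h, nw, seq_len(per_net[[nw]])),
                 network = nw, compartment = "cortical")
    }))
  }))
  sub_structs <- c("HIP", "AMY", "pTHA", "aTHA", "NAc", "GP", "PUT", "CAU")
  subcortical <- do.call(rbind, lapply(c("LH", "RH"), function(h) {
    data.frame(name = paste0(h, "_", sub_structs),
               network = "Subcortical", compartment = "subcortical")
  }))
  tab <- rbind(cortical, subcortical)
  data.frame(index = seq_len(nrow(tab)), tab, row.names = NULL)
}

#' @rdname default_parcellation
#' @param n_regions number of regions; when 116, [default_parcellation()] is
#'   returned.
#' @export
make_parcellation <- function(n_regions) {
  if (n_regions == 116L) return(default_parcellation())
  networks <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic",
                "Cont", "Default")
  data.frame(index = seq_len(n_regions),
             name = sprintf("R%03d", seq_len(n_regions)),
             network = networks[(seq_len(n_regions) - 1L) %% 7L + 1L],
             compartment = "cortical")
}

#' Read / write a parcellation table (TSV)
#'
#' Columns: `index  name  network  compartment`.
#'
#' @param path file path.
#' @return [read_parcellation()] returns the validated data frame.
#' @export
read_parcellation <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("index", "name", "network", "compartment")
  if (!all(need %in% names(tab))) {
    stop_invalid("parcellation table must have columns: ",
                 paste(need, collapse = ", "))
  }
  if (any(tab$index != seq_len(nrow(tab)))) {
    stop_invalid("parcellation indices must be 1..n in order")
  }
  tab
}

#' @rdname read_parcellation
#' @param parcellation a parcellation data frame.
#' @export
write_parcellation <- function(parcellation, path) {
  utils::write.table(parcellation, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
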