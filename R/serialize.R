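# Self-contained text serialization for ensembles: a header of key=value
# lines, then each member's metadata, withheld ids and flattened trees.
# Doubles are written with %.17g so a write/read round trip is exact.

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a BRT ensemble to a plain-text file
#'
#' @param ensemble A `brt_ensemble`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_ensemble()] for the exact-round-trip reader.
#' @export
write_ensemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("rangedrivers_ensemble 1")
  wl("n_sims=", ensemble$n_sims)
  wl("holdout=", .fmt_num(ensemble$holdout))
  wl("tc=", ensemble$tc)
  wl("lr=", .fmt_num(ensemble$lr))
  wl("bag_fraction=", .fmt_num(ensemble$bag_fraction))
  wl("n_trees=", ensemble$n_trees)
  wl("seed=", ensemble$seed)
  wl("vars=", paste(ensemble$schema$vars, collapse = ","))
  wl("log_vars=", paste(ensemble$schema$log_vars, collapse = ","))
  for (m in ensemble$members) {
    wl("member intercept=", .fmt_num(m$fit$intercept),
       " auc=", .fmt_num(m$auc),
       " dev_expl=", .fmt_num(m$dev_expl),
       " n_trees=", m$fit$n_trees,
       " seed=", m$fit$seed)
    wl("withheld ", paste(m$withheld_ids, collapse = ","))
    for (tree in m$fit$trees) {
      wl("tree ", nrow(tree))
      for (r in seq_len(nrow(tree)))
        wl(paste(.fmt_num(tree[r, ]), collapse = " "))
    }
  }
  invisible(path)
}

#' Read a BRT ensemble written by [write_ensemble()]
#'
#' @param path File path.
#' @return A `brt_ensemble` identical to the one written.
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "rangedrivers_ensemble"))
    stop("not a rangedrivers ensemble file: ", path)
  kv <- function(key) {
    ln <- grep(paste0("^", key, "="), lines[1:10], value = TRUE)[1]
    sub(paste0("^", key, "="), "", ln)
  }
  schema <- list(vars = strsplit(kv("vars"), ",")[[1]],
                 log_vars = strsplit(kv("log_vars"), ",")[[1]])
  hdr <- list(n_sims = as.integer(kv("n_sims")),
              holdout = as.numeric(kv("holdout")),
              tc = as.integer(kv("tc")), lr = as.numeric(kv("lr")),
              bag_fraction = as.numeric(kv("bag_fraction")),
              n_trees = as.integer(kv("n_trees")),
              seed = as.integer(kv("seed")))

  i <- 11L
  members <- list()
  while (i <= length(lines)) {
    stopifnot(startsWith(lines[i], "member "))
    fields <- strsplit(sub("^member ", "", lines[i]), " ")[[1]]
    meta <- as.list(sub("^[a-z_]+=", "", fields))
    names(meta) <- sub("=.*$", "", fields)
    i <- i + 1L
    withheld <- as.integer(strsplit(sub("^withheld ?", "", lines[i]),
                                    ",")[[1]])
    i <- i + 1L
    trees <- list()
    while (i <= length(lines) && startsWith(lines[i], "tree ")) {
      nr <- as.integer(sub("^tree ", "", lines[i]))
      block <- lines[(i + 1L):(i + nr)]
      tree <- matrix(as.numeric(unlist(strsplit(block, " "))),
                     nrow = nr, ncol = 6, byrow = TRUE)
      trees[[length(trees) + 1L]] <- tree
      i <- i + nr + 1L
    }
    fit <- structure(list(intercept = as.numeric(meta$intercept),
                          trees = trees, lr = hdr$lr, tc = hdr$tc,
                          bag_fraction = hdr$bag_fraction,
                          min_node = NA_integer_,
                          n_trees = as.integer(meta$n_trees),
                          schema = schema,
                          seed = as.integer(meta$seed)),
                     class = "brt_fit")
    members[[length(members) + 1L]] <-
      list(fit = fit, withheld_ids = withheld,
           auc = as.numeric(meta$auc),
           dev_expl = as.numeric(meta$dev_expl),
           n_trees = as.integer(meta$n_trees))
  }
  structure(c(list(members = members), hdr, list(schema = schema)),
            class = "brt_ensemble")
}
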