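#' Two-wave snowball sample of a network
#'
#' Emulates the recruitment process of small network studies: the seed is
#' the agent with the highest degree (degree centrality; ties broken
#' uniformly at random), each of its neighbours is recruited with
#' probability `p` (wave 1), and each not-yet-contacted neighbour of a
#' wave-1 recruit is recruited with probability `p` (wave 2). Every agent
#' faces at most one recruitment trial no matter how often it is
#' nominated, and an agent who declines once stays excluded. Recruiters
#' are processed in sampling order and their contacts in ascending agent
#' index, so samples are reproducible from the random seed.
#'
#' Samples with fewer than four agents are rejected: the function signals
#' a condition of class `degroot_rejection` that callers (see
#' [run_cell()]) catch to regenerate the network.
#'
#' @param A True adjacency matrix.
#' @param p Recruitment probability in (0, 1].
#' @return A list of class `snowball_sample` with elements
#'   `sampled_ids` (original agent indices, seed first),
#'   `wave` (named 0/1/2 per sampled agent), `seed_id`, and
#'   `recruitment_edges` (two-column matrix of recruiter, recruit).
#' @export
snowball_sample <- function(A, p = 1) {
  validate_adjacency(A)
  if (p <= 0 || p > 1) stop("`p` must lie in (0, 1]", call. = FALSE)
  N <- nrow(A)
  deg <- rowSums(A) - 1  # off-diagonal degree
  top <- which(deg == max(deg))
  seed <- if (length(top) == 1L) top else top[sample.int(length(top), 1)]

  tried <- rep(FALSE, N)
  tried[seed] <- TRUE
  sampled <- seed
  wave <- c(0L)
  edges <- matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("recruiter", "recruit")))

  recruit_from <- function(recruiter, wave_no) {
    contacts <- which(A[recruiter, ] == 1 & seq_len(N) != recruiter)
    contacts <- sort(contacts[!tried[contacts]])
    for (ag in contacts) {
      tried[ag] <<- TRUE
      if (runif(1) < p || p == 1) {
        sampled <<- c(sampled, ag)
        wave <<- c(wave, wave_no)
        edges <<- rbind(edges, c(recruiter, ag))
      }
    }
  }

  recruit_from(seed, 1L)
  wave1 <- sampled[wave == 1L]
  for (r in wave1) recruit_from(r, 2L)

  if (length(sampled) < 4L) {
    stop(errorCondition(
      sprintf("snowball sample of size %d rejected (minimum 4)",
              length(sampled)),
      class = c("degroot_rejection", "error")))
  }
  names(wave) <- sampled
  structure(list(sampled_ids = sampled, wave = wave, seed_id = seed,
                 recruitment_edges = edges),
            class = "snowball_sample")
}

#' @export
print.snowball_sample <- function(x, ...) {
  cat(sprintf("Snowball sample: seed %d, %d agents (wave 1: %d, wave 2: %d)\n",
              x$seed_id, length(x$sampled_ids),
              sum(x$wave == 1), sum(x$wave == 2)))
  invisible(x)
}

#' Adjacency-matrix varieties for a sampled network
#'
#' A sampled network leaves some links unknown; the adjacency matrix
#' handed to the fitter must nonetheless commit each pair to linked or
#' unlinked. Four varieties span the options:
#'
#' * `correct` — the true adjacency reduced to the sampled agents
#'   (requires link information that is usually unethical or impractical
#'   to collect; a baseline).
#' * `build` — only links known to exist from the recruitment chain:
#'   same-wave links are dropped from `correct`, and each wave-2 agent
#'   keeps a single randomly selected link to a sampled wave-1 true
#'   neighbour (always at least its recruiter).
#' * `remove` — only links known to be absent are dropped: all pairs
#'   within waves 1 and 2 are linked, while the seed keeps exactly its
#'   true links to sampled agents (the seed names all its contacts, so
#'   absent seed links are known absent).
#' * `complete` — every pair linked: a matrix of ones.
#'
#' The varieties nest entrywise: `build <= correct <= remove <= complete`.
#'
#' @param truth True full-network adjacency matrix.
#' @param sample A [snowball_sample()] drawn from `truth`.
#' @param kind One of `"correct"`, `"build"`, `"remove"`, `"complete"`.
#' @return An `M x M` adjacency matrix over the sampled agents, in
#'   sampling order, with unit diagonal.
#' @export
adjacency_variety <- function(truth, sample,
                              kind = c("correct", "build", "remove",
                                       "complete")) {
  kind <- match.arg(kind)
  ids <- sample$sampled_ids
  M <- length(ids)
  correct <- truth[ids, ids, drop = FALSE]
  diag(correct) <- 1
  dimnames(correct) <- list(ids, ids)
  if (kind == "correct") return(correct)
  if (kind == "complete") {
    return(matrix(1, M, M, dimnames = dimnames(correct)))
  }
  wave <- sample$wave  # aligned with ids
  if (kind == "build") {
    B <- correct
    same_wave <- outer(wave, wave, "==") & wave > 0
    diag(same_wave) <- FALSE
    B[same_wave] <- 0
    w1 <- which(wave == 1L)
    for (k in which(wave == 2L)) {
      linked_w1 <- w1[B[k, w1] == 1]
      keep <- if (length(linked_w1) > 1L)
        linked_w1[sample.int(length(linked_w1), 1)] else linked_w1
      drop_ <- setdiff(linked_w1, keep)
      B[k, drop_] <- 0
      B[drop_, k] <- 0
    }
    return(B)
  }
  # remove: link everything within waves 1 and 2; seed keeps true links
  R <- correct
  nonseed <- which(wave > 0)
  R[nonseed, nonseed] <- 1
  R
}
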