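# Exact Markov chain of the smallest non-trivial pseudocell: two proteins
# (species A and B, with an A-B interaction rule) on a closed 2x2x2
# lattice. The full automaton step (site-by-site interaction phase, then
# site-by-site diffusion phase with rotation, translation and pushes) is
# enumerated analytically over the 80 reachable states, giving exact
# transition probabilities to compare against the stochastic simulator.
#
# State: (pa, pb, bond) with pa, pb site indices 0..7 of instances A and B
# (site = (z*2 + y)*2 + x) and bond in {0, 1} (1 only if face-adjacent).

mc_coords <- function(i) c(i %% 2L, (i %/% 2L) %% 2L, i %/% 4L)
mc_site <- function(x, y, z) (z * 2L + y) * 2L + x

mc_adjacent <- function(i, j) {
  d <- abs(mc_coords(i) - mc_coords(j))
  sum(d) == 1L
}

# face directions in the simulator's order: +x,-x,+y,-y,+z,-z
MC_DIRS <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))

# the six 90-degree rotation generators, same order as the directions
# (+x,-x,+y,-y,+z,-z axes), acting on offset (dx,dy,dz)
mc_rotate <- function(g, v) {
  x <- v[1]; y <- v[2]; z <- v[3]
  switch(g,
    c(x, -z, y),    # +90 about x
    c(x, z, -y),    # -90 about x
    c(z, y, -x),    # +90 about y
    c(-z, y, x),    # -90 about y
    c(-y, x, z),    # +90 about z
    c(y, -x, z))    # -90 about z
}

mc_states <- function() {
  out <- list()
  for (pa in 0:7) for (pb in 0:7) {
    if (pa == pb) next
    out[[length(out) + 1]] <- c(pa, pb, 0L)
    if (mc_adjacent(pa, pb)) out[[length(out) + 1]] <- c(pa, pb, 1L)
  }
  do.call(rbind, out)
}

mc_key <- function(s) paste(s[1], s[2], s[3])

# one interaction-phase site visit acting on the bond variable:
# 2x2 row-stochastic matrix over bond in {0,1}
mc_visit_matrix <- function(adjacent, p_on, p_off) {
  if (!adjacent) return(diag(2))
  rbind(
    c(1 - p_on, p_on),                                  # from unbonded
    c(p_off * (1 - p_on), 1 - p_off + p_off * p_on))    # from bonded
}

# full interaction phase: both occupied sites visited in raster order;
# positions unchanged, only the bond evolves
mc_interaction_row <- function(s, p_on, p_off, states) {
  M <- mc_visit_matrix(mc_adjacent(s[1], s[2]), p_on, p_off)
  P2 <- M %*% M
  row <- setNames(numeric(nrow(states)), apply(states, 1, mc_key))
  for (b2 in 0:1) {
    pr <- P2[s[3] + 1, b2 + 1]
    if (pr > 0) row[mc_key(c(s[1], s[2], b2))] <- row[mc_key(c(s[1], s[2], b2))] + pr
  }
  row
}

mc_in_bounds <- function(v) all(v >= 0 & v <= 1)

# exact diffusion phase by recursive enumeration of the site raster.
# Returns a named probability vector over final states.
mc_diffusion_row <- function(s, states) {
  acc <- new.env()
  emit <- function(pa, pb, bond, pr) {
    k <- mc_key(c(pa, pb, bond))
    acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) + pr
  }
  # dimer action: rotation w.p. 1/2 (diameter 2), then translation w.p.
  # 1/2 (mass 2); no other complexes exist, so no pushes
  dimer_act <- function(pa, pb, pr, cont) {
    ca <- mc_coords(pa); cb <- mc_coords(pb)
    after_rot <- list()
    push_out <- function(lst, a, b, p) {
      k <- paste(a, b)
      lst[[k]] <- if (is.null(lst[[k]])) p else lst[[k]] + p
      lst
    }
    after_rot <- push_out(after_rot, pa, pb, 0.5)   # no rotation
    ctr <- (ca + cb) / 2
    piv <- floor(ctr + 0.5)
    for (g in 1:6) {
      na_ <- piv + mc_rotate(g, ca - piv)
      nb_ <- piv + mc_rotate(g, cb - piv)
      if (mc_in_bounds(na_) && mc_in_bounds(nb_)) {
        after_rot <- push_out(after_rot, mc_site(na_[1], na_[2], na_[3]),
                              mc_site(nb_[1], nb_[2], nb_[3]), 0.5 / 6)
      } else {
        after_rot <- push_out(after_rot, pa, pb, 0.5 / 6)  # rejected
      }
    }
    for (k1 in names(after_rot)) {
      ab <- as.integer(strsplit(k1, " ")[[1]])
      p1 <- after_rot[[k1]]
      # translation
      cont(ab[1], ab[2], p1 * 0.5)                  # not attempted
      ca2 <- mc_coords(ab[1]); cb2 <- mc_coords(ab[2])
      for (d in 1:6) {
        na_ <- ca2 + MC_DIRS[d, ]; nb_ <- cb2 + MC_DIRS[d, ]
        if (mc_in_bounds(na_) && mc_in_bounds(nb_)) {
          cont(mc_site(na_[1], na_[2], na_[3]),
               mc_site(nb_[1], nb_[2], nb_[3]), p1 * 0.5 / 6)
        } else {
          cont(ab[1], ab[2], p1 * 0.5 / 6)          # rejected at the wall
        }
      }
    }
  }
  # monomer action: rotation is positionally inert; translation w.p. 1,
  # uniform direction; a blocking monomer is pushed with probability 1
  monomer_act <- function(me, other, pr, cont) {
    cm <- mc_coords(me)
    for (d in 1:6) {
      t1 <- cm + MC_DIRS[d, ]
      p1 <- pr / 6
      if (!mc_in_bounds(t1)) { cont(me, other, p1); next }
      t1s <- mc_site(t1[1], t1[2], t1[3])
      if (t1s == other) {
        t2 <- mc_coords(other) + MC_DIRS[d, ]
        if (!mc_in_bounds(t2)) { cont(me, other, p1); next }  # push fails
        cont(t1s, mc_site(t2[1], t2[2], t2[3]), p1)
      } else {
        cont(t1s, other, p1)
      }
    }
  }
  walk <- function(v, pa, pb, bond, actedA, actedB, pr) {
    if (v > 7) { emit(pa, pb, bond, pr); return(invisible()) }
    if (bond == 1L) {
      acted <- actedA   # single flag for the dimer
      if ((pa == v || pb == v) && !acted) {
        dimer_act(pa, pb, pr, function(na_, nb_, p2)
          walk(v + 1L, na_, nb_, 1L, TRUE, TRUE, p2))
      } else {
        walk(v + 1L, pa, pb, bond, actedA, actedB, pr)
      }
    } else if (pa == v && !actedA) {
      monomer_act(pa, pb, pr, function(nme, noth, p2)
        walk(v + 1L, nme, noth, 0L, TRUE, actedB, p2))
    } else if (pb == v && !actedB) {
      monomer_act(pb, pa, pr, function(nme, noth, p2)
        walk(v + 1L, noth, nme, 0L, actedA, TRUE, p2))
    } else {
      walk(v + 1L, pa, pb, bond, actedA, actedB, pr)
    }
  }
  walk(0L, s[1], s[2], s[3], FALSE, FALSE, 1)
  row <- setNames(numeric(nrow(states)), apply(states, 1, mc_key))
  for (k in ls(acc)) row[k] <- acc[[k]]
  row
}

# full step transition matrix and its stationary distribution
mc_build_chain <- function(p_on, p_off) {
  states <- mc_states()
  keys <- apply(states, 1, mc_key)
  n <- nrow(states)
  Tint <- matrix(0, n, n, dimnames = list(keys, keys))
  Tdif <- matrix(0, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n)) {
    Tint[i, ] <- mc_interaction_row(states[i, ], p_on, p_off, states)
    Tdif[i, ] <- mc_diffusion_row(states[i, ], states)
  }
  Tstep <- Tint %*% Tdif
  # stationary distribution by power iteration
  pi0 <- rep(1 / n, n)
  for (it in 1:4000) {
    pi1 <- as.numeric(pi0 %*% Tstep)
    if (max(abs(pi1 - pi0)) < 1e-14) { pi0 <- pi1; break }
    pi0 <- pi1
  }
  list(states = states, keys = keys, T_int = Tint, T_dif = Tdif,
       T_step = Tstep, pi = setNames(pi0, keys))
}

# coarse observable: bonded / unbonded-adjacent / unbonded-apart
mc_category <- function(pa, pb, bond) {
  if (bond == 1L) "bonded"
  else if (mc_adjacent(pa, pb)) "adjacent"
  else "apart"
}

mc_category_probs <- function(chain) {
  cats <- apply(chain$states, 1, function(s) mc_category(s[1], s[2], s[3]))
  tapply(chain$pi, cats, sum)
}
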