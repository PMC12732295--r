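# Published steady-state tables used as acceptance fixtures.
# Counts n, n0, n1_0 are per 10^6 cells; fr* are percent fractions of empty
# cells by type. Both tables share c0 = 1, c1 = 0.5.

table1 <- data.frame(
  c2   = c(0, 0, 0.5, 0.5, 0, 0, 0.5, 0.5),
  c3   = c(0, 0.5, 0, 0.5, 0, 0.5, 0, 0.5),
  delta = c(0.4, 0.4, 0.4, 0.4, 0.5, 0.5, 0.5, 0.5),
  rho  = c(0.486071, 0.535833, 0.572665, 0.611689,
           0.454748, 0.491362, 0.529656, 0.560624),
  n    = c(282836, 188651, 80101, 3026, 268644, 200036, 99161, 40520),
  n0   = c(94017, 58676, 85192, 49310, 71715, 45848, 67423, 40364),
  n1_0 = c(62962, 40925, 68729, 43122, 52926, 37211, 58232, 39847),
  fr0  = c(22.0, 25.1, 22.6, 26.0, 24.6, 27.0, 25.0, 27.6),
  fr1  = c(31.6, 33.4, 31.0, 33.7, 34.1, 35.3, 33.7, 35.5),
  fr2  = c(34.1, 32.7, 30.3, 29.2, 31.5, 30.4, 28.9, 27.8),
  fr3  = c(12.3, 8.8, 16.0, 11.1, 9.7, 7.3, 12.4, 9.1))

table2 <- data.frame(
  delta = c(0.12125, 0.1225, 0.125, 0.13, 0.14, 0.16, 0.2, 0.28, 0.44,
            0.6, 0.606),
  rho  = c(0.757612, 0.756087, 0.753067, 0.747144, 0.735742, 0.714519,
           0.679159, 0.617352, 0.532158, 0.472464, 0.470552),
  n    = c(170, 1619, 4468, 9975, 20277, 38428, 74594, 105782, 145624,
           163658, 164103),
  n0   = c(97886, 98078, 98441, 99093, 100122, 101253, 97998, 93677,
           70266, 44557, 43605),
  n1_0 = c(78924, 78976, 79065, 79192, 79259, 78807, 74515, 69294, 55024,
           43953, 43598),
  fr0  = c(16.1, 16.1, 16.2, 16.4, 16.7, 17.3, 18.8, 20.6, 24.4, 27.7, 27.8),
  fr1  = c(19.6, 19.7, 19.9, 20.2, 20.8, 22.0, 24.5, 27.9, 33.0, 36.1, 36.2),
  fr2  = c(31.7, 31.8, 31.9, 32.1, 32.4, 33.0, 33.5, 33.4, 30.9, 27.9, 27.8),
  fr3  = c(32.6, 32.4, 32.0, 31.3, 30.0, 27.6, 23.2, 18.1, 11.8, 8.3, 8.2))

params_set1 <- function(delta) rda_params(1, 0.5, 0.5, 0.5, delta = delta)
params_set2 <- function(delta) rda_params(1, 0.5, 0.25, 0.125, delta = delta)
params_t1 <- function(row)
  rda_params(1, 0.5, table1$c2[row], table1$c3[row], delta = table1$delta[row])

# fields of a steady state as a plain vector for comparisons
state_summary <- function(st)
  c(rho = st$rho, n = st$n, n0 = st$n0, n1_0 = st$n1_0,
    fr = c(st$x0, st$x1, st$x2, st$x3) / ((1 - st$rho) * st$N) * 100)
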