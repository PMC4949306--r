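# Reference tables for the worked example V = C = 0.1, T = 20, initial
# RHP 10 (8 x 8 grid of concession classes k = 1..8). Values as printed in
# the original report of this example; see the acceptance tests.

reference_log_matrix <- matrix(byrow = TRUE, nrow = 8, c(
  3.2000, 2.8700, 2.7300, 2.6500, 2.6000, 2.5800, 2.5600, 2.5400,
  3.4400, 3.0600, 2.8700, 2.7600, 2.7000, 2.6600, 2.6200, 2.6000,
  3.5000, 3.1000, 2.8900, 2.7700, 2.6900, 2.6500, 2.6100, 2.6000,
  3.5100, 3.0800, 2.8700, 2.7400, 2.6700, 2.6200, 2.5600, 2.5600,
  3.5000, 3.0500, 2.8400, 2.7000, 2.6200, 2.5700, 2.5400, 2.5200,
  3.4600, 3.0200, 2.7900, 2.6600, 2.6000, 2.5300, 2.5000, 2.4700,
  3.4300, 2.9900, 2.7700, 2.6200, 2.5600, 2.5000, 2.4800, 2.4500,
  3.4200, 2.9500, 2.7300, 2.6000, 2.5100, 2.4800, 2.4400, 2.4100))

reference_share_matrix <- matrix(byrow = TRUE, nrow = 8, c(
  0.5000, 0.4585, 0.4417, 0.4353, 0.4344, 0.4354, 0.4360, 0.4385,
  0.5415, 0.5000, 0.4825, 0.4777, 0.4765, 0.4777, 0.4806, 0.4825,
  0.5583, 0.5175, 0.5000, 0.4941, 0.4928, 0.4949, 0.4973, 0.4999,
  0.5647, 0.5223, 0.5059, 0.5000, 0.4992, 0.5013, 0.5034, 0.5066,
  0.5656, 0.5235, 0.5072, 0.5008, 0.5000, 0.5014, 0.5046, 0.5077,
  0.5646, 0.5223, 0.5051, 0.4987, 0.4986, 0.5000, 0.5026, 0.5054,
  0.5640, 0.5194, 0.5027, 0.4966, 0.4954, 0.4974, 0.5000, 0.5033,
  0.5615, 0.5175, 0.5001, 0.4934, 0.4923, 0.4946, 0.4967, 0.5000))

# representative-threshold ladder for V = C = 0.1 (2 dp)
reference_theta_ladder <- c(0.91, 0.74, 0.61, 0.50, 0.41, 0.33, 0.27, 0.22)

standard_params <- function(T = 20) game_params(V = 0.1, C = 0.1, T = T)
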