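# Example reacharm run configuration.
#
# Any key may be omitted; omitted keys take the package defaults (see
# reacharm::default_config() for the full schema with every default).
# Unknown keys are rejected by name.

internal:
  m: 3            # internal-model point mass (kg)
  tau: 0.030      # abstract muscle activation time constant (s)
  fmax: 1000      # abstract maximum muscle force (N)
  dt: 0.005       # control/integration step (s)
  steps: 221      # total simulation steps
  dwell: 21       # terminal dwell steps with active state penalty
  delay: 0.050    # sensory delay (s), integer multiple of dt

robot:
  base_x: 0.0     # robot base, world frame (m)
  base_y: 0.75

nmpc:
  Np: 50          # prediction horizon (steps)

impedance:
  kp: 50          # end-effector stiffness (N/m)
  kd: 10          # end-effector damping (N s/m)
  time_shift: 0.050

scenario:
  type: reach     # reach | center_out
  robot_mode: none  # none | off | nmpc | impedance
  target_x: -0.25
  target_y: 0.40
  field_b: 0      # curl-field gain (N s/m)
  noise: false
  seed: 1
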