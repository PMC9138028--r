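# Default coarse-grained parameterisation of the collagen model.
# Any key may be omitted; omitted keys keep these values.
molecule:
  n_beads: 218
  L0: 3011          # molecule length along the principal axis [A]
  r0: 14.00         # bond equilibrium distance [A]
  r1: 18.20         # hyperelastic onset distance [A]
  rb: 21.00         # bond breaking distance [A]
  KT0: 17.13        # soft-branch stiffness [kcal/mol/A^2]
  KT1: 97.66        # stiff-branch stiffness [kcal/mol/A^2]
  Ktheta: 14.98     # bending stiffness [kcal/mol/rad^2]
  theta0_min: 164   # equilibrium bending angles [deg]
  theta0_max: 180
  D_mol: 16.52      # molecule diameter [A]
  mass_total: 287000
  n_amino_acids: 3134
lennard_jones:
  epsilon: 6.87     # well depth [kcal/mol]
  sigma: 14.72      # zero-crossing distance [A]
crosslink:
  divalent:
    r0: 10.00
    r1: 12.00
    rb: 14.68
    KT0: 0.20
    KT1: 41.84
  trivalent:
    r0: 8.60
    r1: 12.20
    rb: 14.89
    KT0: 0.20
    KT1: 54.60
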