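#pragma once
#include <cmath>

// Photon interaction physics for water at PET energies (keV, mm).
// Compton from the analytically integrated Klein-Nishina cross-section,
// photoelectric from an E^-3 fit anchored on tabulated water attenuation;
// the photoelectric channel is negligible above 350 keV but kept so that
// low-energy tracked photons terminate physically.
namespace pet {

const double MEC2 = 511.0;             // electron rest energy (keV), as used in Eq. kinematics
const double RE2_MM2 = 7.940787e-24;   // classical electron radius squared (mm^2)
const double NE_WATER = 3.3428e20;     // electron density of water (mm^-3)
const double KPE_WATER = 276.0;        // photoelectric fit: mu_pe = KPE/E^3 (mm^-1, E in keV)

inline double compton_eprime(double E, double cost) {
  return E / (1.0 + (E / MEC2) * (1.0 - cost));
}

// total Klein-Nishina cross-section per electron (mm^2)
inline double kn_total_sigma(double E) {
  double a = E / MEC2;
  double l = std::log(1.0 + 2.0 * a);
  double term = (1.0 + a) / (a * a) *
                    (2.0 * (1.0 + a) / (1.0 + 2.0 * a) - l / a) +
                l / (2.0 * a) -
                (1.0 + 3.0 * a) / ((1.0 + 2.0 * a) * (1.0 + 2.0 * a));
  return 2.0 * M_PI * RE2_MM2 * term;
}

inline double mu_compton_water(double E) { return NE_WATER * kn_total_sigma(E); }
inline double mu_photo_water(double E) { return KPE_WATER / (E * E * E); }
inline double mu_total_water(double E) { return mu_compton_water(E) + mu_photo_water(E); }

}  // namespace pet
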