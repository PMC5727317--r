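// Straight-line flux evaluation for the 29-state binding chain.
// Enumerates the same transitions as the R-level binding_transitions():
// C6 <-> C6A2 at h_A*A^2 / f_A; KaiB on at (6-i)*h_B*B, off at
// (i-j)*f_B; KaiA onto bound KaiB at (i-j)*h_BA*A^2, off at j*f_BA.
// Constant indices follow the canonical layout sidx(i,j)=1+i(i+1)/2+j.
#ifndef KAIABC_FLUX_H
#define KAIABC_FLUX_H
static inline void binding_flux(const double *p, const double rHA,
                                const double rFA, const double rHB,
                                const double rFB, const double rBA,
                                const double rFBA, double *d) {
  for (int s = 0; s < 29; ++s) d[s] = 0.0;
        { const double fl = rHA * p[1]; d[1] -= fl; d[0] += fl; }
        { const double fl = rFA * p[0]; d[0] -= fl; d[1] += fl; }
        { const double fl = 6.0 * rHB * p[1]; d[1] -= fl; d[2] += fl; }
        { const double fl = 5.0 * rHB * p[2]; d[2] -= fl; d[4] += fl; }
        { const double fl = 1.0 * rFB * p[2]; d[2] -= fl; d[1] += fl; }
        { const double fl = 1.0 * rBA * p[2]; d[2] -= fl; d[3] += fl; }
        { const double fl = 5.0 * rHB * p[3]; d[3] -= fl; d[5] += fl; }
        { const double fl = 1.0 * rFBA * p[3]; d[3] -= fl; d[2] += fl; }
        { const double fl = 4.0 * rHB * p[4]; d[4] -= fl; d[7] += fl; }
        { const double fl = 2.0 * rFB * p[4]; d[4] -= fl; d[2] += fl; }
        { const double fl = 2.0 * rBA * p[4]; d[4] -= fl; d[5] += fl; }
        { const double fl = 4.0 * rHB * p[5]; d[5] -= fl; d[8] += fl; }
        { const double fl = 1.0 * rFB * p[5]; d[5] -= fl; d[3] += fl; }
        { const double fl = 1.0 * rBA * p[5]; d[5] -= fl; d[6] += fl; }
        { const double fl = 1.0 * rFBA * p[5]; d[5] -= fl; d[4] += fl; }
        { const double fl = 4.0 * rHB * p[6]; d[6] -= fl; d[9] += fl; }
        { const double fl = 2.0 * rFBA * p[6]; d[6] -= fl; d[5] += fl; }
        { const double fl = 3.0 * rHB * p[7]; d[7] -= fl; d[11] += fl; }
        { const double fl = 3.0 * rFB * p[7]; d[7] -= fl; d[4] += fl; }
        { const double fl = 3.0 * rBA * p[7]; d[7] -= fl; d[8] += fl; }
        { const double fl = 3.0 * rHB * p[8]; d[8] -= fl; d[12] += fl; }
        { const double fl = 2.0 * rFB * p[8]; d[8] -= fl; d[5] += fl; }
        { const double fl = 2.0 * rBA * p[8]; d[8] -= fl; d[9] += fl; }
        { const double fl = 1.0 * rFBA * p[8]; d[8] -= fl; d[7] += fl; }
        { const double fl = 3.0 * rHB * p[9]; d[9] -= fl; d[13] += fl; }
        { const double fl = 1.0 * rFB * p[9]; d[9] -= fl; d[6] += fl; }
        { const double fl = 1.0 * rBA * p[9]; d[9] -= fl; d[10] += fl; }
        { const double fl = 2.0 * rFBA * p[9]; d[9] -= fl; d[8] += fl; }
        { const double fl = 3.0 * rHB * p[10]; d[10] -= fl; d[14] += fl; }
        { const double fl = 3.0 * rFBA * p[10]; d[10] -= fl; d[9] += fl; }
        { const double fl = 2.0 * rHB * p[11]; d[11] -= fl; d[16] += fl; }
        { const double fl = 4.0 * rFB * p[11]; d[11] -= fl; d[7] += fl; }
        { const double fl = 4.0 * rBA * p[11]; d[11] -= fl; d[12] += fl; }
        { const double fl = 2.0 * rHB * p[12]; d[12] -= fl; d[17] += fl; }
        { const double fl = 3.0 * rFB * p[12]; d[12] -= fl; d[8] += fl; }
        { const double fl = 3.0 * rBA * p[12]; d[12] -= fl; d[13] += fl; }
        { const double fl = 1.0 * rFBA * p[12]; d[12] -= fl; d[11] += fl; }
        { const double fl = 2.0 * rHB * p[13]; d[13] -= fl; d[18] += fl; }
        { const double fl = 2.0 * rFB * p[13]; d[13] -= fl; d[9] += fl; }
        { const double fl = 2.0 * rBA * p[13]; d[13] -= fl; d[14] += fl; }
        { const double fl = 2.0 * rFBA * p[13]; d[13] -= fl; d[12] += fl; }
        { const double fl = 2.0 * rHB * p[14]; d[14] -= fl; d[19] += fl; }
        { const double fl = 1.0 * rFB * p[14]; d[14] -= fl; d[10] += fl; }
        { const double fl = 1.0 * rBA * p[14]; d[14] -= fl; d[15] += fl; }
        { const double fl = 3.0 * rFBA * p[14]; d[14] -= fl; d[13] += fl; }
        { const double fl = 2.0 * rHB * p[15]; d[15] -= fl; d[20] += fl; }
        { const double fl = 4.0 * rFBA * p[15]; d[15] -= fl; d[14] += fl; }
        { const double fl = 1.0 * rHB * p[16]; d[16] -= fl; d[22] += fl; }
        { const double fl = 5.0 * rFB * p[16]; d[16] -= fl; d[11] += fl; }
        { const double fl = 5.0 * rBA * p[16]; d[16] -= fl; d[17] += fl; }
        { const double fl = 1.0 * rHB * p[17]; d[17] -= fl; d[23] += fl; }
        { const double fl = 4.0 * rFB * p[17]; d[17] -= fl; d[12] += fl; }
        { const double fl = 4.0 * rBA * p[17]; d[17] -= fl; d[18] += fl; }
        { const double fl = 1.0 * rFBA * p[17]; d[17] -= fl; d[16] += fl; }
        { const double fl = 1.0 * rHB * p[18]; d[18] -= fl; d[24] += fl; }
        { const double fl = 3.0 * rFB * p[18]; d[18] -= fl; d[13] += fl; }
        { const double fl = 3.0 * rBA * p[18]; d[18] -= fl; d[19] += fl; }
        { const double fl = 2.0 * rFBA * p[18]; d[18] -= fl; d[17] += fl; }
        { const double fl = 1.0 * rHB * p[19]; d[19] -= fl; d[25] += fl; }
        { const double fl = 2.0 * rFB * p[19]; d[19] -= fl; d[14] += fl; }
        { const double fl = 2.0 * rBA * p[19]; d[19] -= fl; d[20] += fl; }
        { const double fl = 3.0 * rFBA * p[19]; d[19] -= fl; d[18] += fl; }
        { const double fl = 1.0 * rHB * p[20]; d[20] -= fl; d[26] += fl; }
        { const double fl = 1.0 * rFB * p[20]; d[20] -= fl; d[15] += fl; }
        { const double fl = 1.0 * rBA * p[20]; d[20] -= fl; d[21] += fl; }
        { const double fl = 4.0 * rFBA * p[20]; d[20] -= fl; d[19] += fl; }
        { const double fl = 1.0 * rHB * p[21]; d[21] -= fl; d[27] += fl; }
        { const double fl = 5.0 * rFBA * p[21]; d[21] -= fl; d[20] += fl; }
        { const double fl = 6.0 * rFB * p[22]; d[22] -= fl; d[16] += fl; }
        { const double fl = 6.0 * rBA * p[22]; d[22] -= fl; d[23] += fl; }
        { const double fl = 5.0 * rFB * p[23]; d[23] -= fl; d[17] += fl; }
        { const double fl = 5.0 * rBA * p[23]; d[23] -= fl; d[24] += fl; }
        { const double fl = 1.0 * rFBA * p[23]; d[23] -= fl; d[22] += fl; }
        { const double fl = 4.0 * rFB * p[24]; d[24] -= fl; d[18] += fl; }
        { const double fl = 4.0 * rBA * p[24]; d[24] -= fl; d[25] += fl; }
        { const double fl = 2.0 * rFBA * p[24]; d[24] -= fl; d[23] += fl; }
        { const double fl = 3.0 * rFB * p[25]; d[25] -= fl; d[19] += fl; }
        { const double fl = 3.0 * rBA * p[25]; d[25] -= fl; d[26] += fl; }
        { const double fl = 3.0 * rFBA * p[25]; d[25] -= fl; d[24] += fl; }
        { const double fl = 2.0 * rFB * p[26]; d[26] -= fl; d[20] += fl; }
        { const double fl = 2.0 * rBA * p[26]; d[26] -= fl; d[27] += fl; }
        { const double fl = 4.0 * rFBA * p[26]; d[26] -= fl; d[25] += fl; }
        { const double fl = 1.0 * rFB * p[27]; d[27] -= fl; d[21] += fl; }
        { const double fl = 1.0 * rBA * p[27]; d[27] -= fl; d[28] += fl; }
        { const double fl = 5.0 * rFBA * p[27]; d[27] -= fl; d[26] += fl; }
        { const double fl = 6.0 * rFBA * p[28]; d[28] -= fl; d[27] += fl; }
}
#endif
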