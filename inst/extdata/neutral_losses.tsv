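name	formula	radical	nominal
H	H	TRUE	1
H2O	H2O	FALSE	18
CO	CO	FALSE	28
CO2	CO2	FALSE	44
CH2	CH2	FALSE	14
CH3	CH3	TRUE	15
CH4	CH4	FALSE	16
O	O	FALSE	16
CH2O	CH2O	FALSE	30
OCH3	CH3O	TRUE	31
CH3OH	CH4O	FALSE	32
NH3	NH3	FALSE	17
CHO	CHO	TRUE	29
COOH	CHO2	TRUE	45
HCOOH	CH2O2	FALSE	46
C2H2	C2H2	FALSE	26
C2H2O	C2H2O	FALSE	42
C3H6	C3H6	FALSE	42
C4H8	C4H8	FALSE	56
C6H12	C6H12	FALSE	84
Me2NH	C2H7N	FALSE	45
MeNH2	CH5N	FALSE	31
Glc	C6H10O5	FALSE	162
Rha	C6H10O4	FALSE	146
Ara	C5H8O4	FALSE	132
Glua	C6H8O6	FALSE	176
caffeoyl	C9H6O3	FALSE	162
C8H6O	C8H6O	FALSE	118
C8H8O	C8H8O	FALSE	120
C7H4O4	C7H4O4	FALSE	152
C6H6O	C6H6O	FALSE	94
C9H8O3	C9H8O3	FALSE	164
C9H8O4	C9H8O4	FALSE	180
C8H6O4	C8H6O4	FALSE	166
C3H2O3	C3H2O3	FALSE	86
C3H4O3	C3H4O3	FALSE	88
C9H10O2	C9H10O2	FALSE	150
C11H13NO2	C11H13NO2	FALSE	191
C7H10O5	C7H10O5	FALSE	174
C6H4O4	C6H4O4	FALSE	140
C7H4O5	C7H4O5	FALSE	168
C12H14O2	C12H14O2	FALSE	190
C5H8O4	C5H8O4	FALSE	132
C7H6O	C7H6O	FALSE	106
C8H18O3	C8H18O3	FALSE	162
C4H14O3	C4H14O3	FALSE	110
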