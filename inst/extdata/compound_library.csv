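name,formula,class,intrinsic_cation,rt_min
betaine,C5H11NO2,amino_acid,FALSE,0.80
arginine,C6H14N4O2,amino_acid,FALSE,0.95
adenine,C5H5N5,nucleoside,FALSE,1.30
proline,C5H9NO2,amino_acid,FALSE,1.50
pyroglutamic_acid,C5H7NO3,amino_acid,FALSE,1.70
leucine,C6H13NO2,amino_acid,FALSE,2.10
tyrosine,C9H11NO3,amino_acid,FALSE,2.30
adenosine,C10H13N5O4,nucleoside,FALSE,2.50
phenylalanine,C9H11NO2,amino_acid,FALSE,2.80
tryptophan,C11H12N2O2,amino_acid,FALSE,3.20
gallic_acid,C7H6O5,phenolic_acid,FALSE,3.50
rehmannioside_D,C27H42O20,iridoid,FALSE,3.70
neochlorogenic_acid,C16H18O9,quinic_acid_derivative,FALSE,3.90
geniposidic_acid,C16H22O10,iridoid,FALSE,4.20
magnocurarine,C19H24NO3,benzylisoquinoline,TRUE,4.40
chlorogenic_acid,C16H18O9,quinic_acid_derivative,FALSE,4.60
phellodendrine,C20H24NO4,tetrahydroprotoberberine,TRUE,4.90
cianidanol,C15H14O6,flavanol,FALSE,5.00
cryptochlorogenic_acid,C16H18O9,quinic_acid_derivative,FALSE,5.20
procyanidin_B1,C30H26O12,flavanol,FALSE,5.40
caffeic_acid,C9H8O4,phenolic_acid,FALSE,5.60
magnoflorine,C20H24NO4,aporphine,TRUE,5.80
echinacoside,C35H46O20,phenylethanoid_glycoside,FALSE,5.90
daidzin,C21H20O9,isoflavone,FALSE,6.00
epicatechin,C15H14O6,flavanol,FALSE,6.10
tetrahydroxystilbene_glucoside,C20H22O9,stilbene,FALSE,6.20
ferulic_acid,C10H10O4,phenolic_acid,FALSE,6.30
columbamine,C20H20NO4,protoberberine,TRUE,6.50
tubuloside_A,C37H48O21,phenylethanoid_glycoside,FALSE,6.60
yuanhunine,C21H25NO4,tetrahydroprotoberberine,FALSE,6.80
hyperoside,C21H20O12,flavonol,FALSE,6.90
jateorhizine,C20H20NO4,protoberberine,TRUE,7.00
rutin,C27H30O16,flavonol,FALSE,7.05
acteoside,C29H36O15,phenylethanoid_glycoside,FALSE,7.10
berberrubine,C19H15NO4,protoberberine,FALSE,7.20
isoquercetin,C21H20O12,flavonol,FALSE,7.40
epiberberine,C20H18NO4,protoberberine,TRUE,7.60
cosmosiin,C21H20O10,flavone,FALSE,7.90
coptisine,C19H14NO4,protoberberine,TRUE,8.00
beta_ecdysterone,C27H44O7,steroid,FALSE,8.10
astragalin,C21H20O11,flavonol,FALSE,8.20
berberine,C20H18NO4,protoberberine,TRUE,8.40
azelaic_acid,C9H16O4,aliphatic_acid,FALSE,8.50
quercitrin,C21H20O11,flavonol,FALSE,8.70
daidzein,C15H10O4,isoflavone,FALSE,8.90
angelicin,C11H6O3,coumarin,FALSE,9.00
ginsenoside_Re,C48H82O18,triterpenoid_saponin,FALSE,9.20
calycosin,C16H12O5,isoflavone,FALSE,9.30
ginsenoside_Rg1,C42H72O14,triterpenoid_saponin,FALSE,9.40
psoralen,C11H6O3,coumarin,FALSE,9.60
eriodictyol,C15H12O6,flavanone,FALSE,9.80
luteolin,C15H10O6,flavone,FALSE,10.10
genistein,C15H10O5,isoflavone,FALSE,10.40
ginsenoside_Rb1,C54H92O23,triterpenoid_saponin,FALSE,10.60
naringenin,C15H12O5,flavanone,FALSE,10.70
rutaevine,C26H30O9,triterpenoid,FALSE,10.90
apigenin,C15H10O5,flavone,FALSE,11.00
quercetin,C15H10O7,flavonol,FALSE,11.20
chikusetsusaponin_IV,C47H74O18,triterpenoid_saponin,FALSE,11.30
baicalein,C15H10O5,flavone,FALSE,11.60
limonin,C26H30O8,triterpenoid,FALSE,11.80
kaempferol,C15H10O6,flavonol,FALSE,12.00
ligustilide,C12H14O2,phthalide,FALSE,12.20
wogonin,C16H12O5,flavone,FALSE,12.40
obacunone,C26H30O7,triterpenoid,FALSE,12.60
aloe_emodin,C15H10O5,anthraquinone,FALSE,12.80
butylphthalide,C12H14O2,phthalide,FALSE,13.10
emodin,C15H10O5,anthraquinone,FALSE,13.50
levistilide_A,C24H28O4,phthalide,FALSE,14.00
physcion,C16H12O5,anthraquinone,FALSE,14.20
schizandrin_A,C24H32O6,lignan,FALSE,14.70
palmitic_acid,C16H32O2,aliphatic_acid,FALSE,15.50
oleanolic_acid,C30H48O3,triterpenoid,FALSE,15.90
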