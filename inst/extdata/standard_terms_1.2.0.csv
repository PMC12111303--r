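category,st_id,label,rp
BDF,0069,Tablet,1
BDF,0058,Lozenge,2
BDF,0051,Capsule,3
BDF,0050,Cachet,3.5
BDF,0060,Pastille,4
BDF,0054,Gum,5
BDF,0064,Pillules,6
BDF,0062,Pellets,7
BDF,0053,Granules,7.2
BDF,0066,Powder,8
BDF,0059,Lyophilisate,10
BDF,0052,Film,11
BDF,0114,Herbal material (unprocessed),12
BDF,0070,Tea,13
BDF,0085,Suspension,15
BDF,0079,Dispersion,15.5
BDF,0080,Emulsion,16
BDF,0090,Drops,18
BDF,0082,Liquid,18.5
BDF,0084,Solvent,19
BDF,0083,Solution,19.5
BDF,0086,Syrup,20
BDF,0078,Concentrate,20.5
BDF,0094,Spray (unspecified),22
BDF,0081,Lacquer,23
BDF,0077,Collodion,24
BDF,0093,Shampoo,25
BDF,0073,Gel,26
BDF,0072,Foam,26.5
BDF,0071,Cream,27
BDF,0074,Ointment,29
BDF,0076,Poultice,30
BDF,0075,Paste,31
BDF,0065,Plaster,33
BDF,0061,Patch,33.5
BDF,0056,Impregnated material,36
BDF,0067,Stick,36.5
BDF,0103,Cement,38
BDF,0068,Suppository,40.5
BDF,0063,Pessary,41
BDF,0088,Insert,42
BDF,0102,Pouch,42.5
BDF,0055,Implant,43
BDF,0089,Additive (unspecified),44
BDF,0092,Radiopharmaceutical,45
BDF,0095,System,46
BDF,0087,Medicinal gas,47
AME,0019,Swallowing,1
AME,0018,Sucking,2
AME,0014,Orodispersion,3
AME,0007,Chewing,4
AME,0008,Gargling,5
AME,0017,Spraying,6
AME,0013,Instillation,7
AME,0015,Rinsing/washing,8
AME,0005,Application,9
AME,0006,Bathing,10
AME,0012,Insertion,11
AME,0011,Injection,12
AME,0009,Infusion,13
AME,0113,Implantation,14
AME,0010,Inhalation,15
AME,0111,Burning,16
AME,0112,Dialysis,17
AME,0004,Administration,18
AME,0020,Not specified,19
ISI,0031,Oral,1
ISI,0032,Oromucosal,2
ISI,0023,Dental,3
ISI,0106,Gastric,4
ISI,0107,Gastroenteral,5
ISI,0108,Intestinal,6
ISI,0035,Rectal,7
ISI,0036,Vaginal,8
ISI,0022,Cutaneous/transdermal,9
ISI,0021,Auricular,10
ISI,0029,Nasal,11
ISI,0030,Ocular,12
ISI,0110,Oculonasal,13
ISI,0034,Pulmonary,14
ISI,0033,Parenteral,15
ISI,0026,Intramammary,16
ISI,0105,Endocervical,17
ISI,0027,Intrauterine,18
ISI,0028,Intravesical/urethral,19
ISI,0109,Intraperitoneal,20
ISI,0024,Environmental,21
ISI,0025,Extracorporeal,22
ISI,0037,Unknown/miscellaneous,23
RCA,0047,Conventional,1
RCA,0045,Prolonged,3
RCA,0046,Modified,6
RCA,0044,Delayed,9
RCA,0048,Unknown,10
TRN,0042,No transformation,1
TRN,0038,Dilution,3
TRN,0040,Dissolution,5
TRN,0039,Dispersion,7
TRN,0041,Mixing,7.5
TRN,0043,Unknown,10
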