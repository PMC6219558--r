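code,binomial,family,phyllotaxis,life_form,leaf_type,venation_class,n_leaves,n_veins
Ame,Amphicarpaea bracteata subsp. edgeworthii var. japonica,Fabaceae,alternate,herbaceous,ternate,basal actinodromous,60,454
Atg,Acer ginnala var. aidzuense,Sapindaceae,opposite,woody,simple,basal actinodromous,15,173
Auc,Aucuba japonica,Aucubaceae,opposite,woody,simple,semicraspedodromous,15,223
Bid,Bidens sp.,Asteraceae,opposite,herbaceous,pinnate,craspedodromous,15,321
Bpt,Betula platyphylla var. japonica,Betulaceae,alternate,woody,simple,craspedodromous,15,199
Cay,Cayratia japonica,Vitaceae,alternate,herbaceous,palmate,craspedodromous,15,179
Ces,Cerasus sargentii,Rosaceae,alternate,woody,simple,semicraspedodromous,15,223
Coc,Cornus controversa,Cornaceae,alternate,woody,simple,eucamptodromous,15,191
Cpa,Chenopodium album,Amaranthaceae,alternate,herbaceous,simple,suprabasal actinodromous,50,234
Cyr,Cynanchum rostellatum,Apocynaceae,opposite,herbaceous,simple,semicraspedodromous,15,225
Elc,Eleutherococcus senticosus,Araliaceae,alternate,woody,palmate,semicraspedodromous,15,195
Eua,Euonymus alatus,Celastraceae,opposite,woody,simple,semicraspedodromous,15,161
Fas,Fallopia sachalinensis,Polygonaceae,alternate,herbaceous,simple,semicraspedodromous,15,306
Fms,Fraxinus mandshurica,Oleaceae,opposite,woody,pinnate,semicraspedodromous,15,344
Hyp,Hydrangea paniculata,Hydrangeaceae,opposite,woody,simple,eucamptodromous,15,155
Jms,Juglans mandshurica var. sachalinensis,Juglandaceae,alternate,woody,pinnate,craspedodromous,15,522
Jpc,Justicia procumbens,Acanthaceae,opposite,herbaceous,simple,eucamptodromous,50,414
Lgo,Ligustrum obtusifolium,Oleaceae,opposite,woody,simple,brochidodromous,15,180
Lon,Lonicera japonica,Caprifoliaceae,opposite,woody,simple,semicraspedodromous,50,418
Mkb,Magnolia kobus var. borealis,Magnoliaceae,alternate,woody,simple,craspedodromous,15,250
Oeb,Oenothera biennis,Onagraceae,alternate,herbaceous,simple,semicraspedodromous,15,354
Pas,Paederia foetida,Rubiaceae,opposite,herbaceous,simple,semicraspedodromous,50,464
Piq,Picrasma quassioides,Simaroubaceae,alternate,woody,pinnate,semicraspedodromous,15,219
Pps,Populus suaveolens,Salicaceae,alternate,woody,simple,craspedodromous,15,161
Qmc,Quercus crispula,Fagaceae,alternate,woody,simple,craspedodromous,15,413
Rhd,Rhododendron brachycarpum,Ericaceae,alternate,woody,simple,craspedodromous,15,350
Scs,Scutellaria strigillosa,Lamiaceae,opposite,herbaceous,simple,semicraspedodromous,50,324
Sol,Solanum sp.,Solanaceae,alternate,herbaceous,simple,semicraspedodromous,50,347
Sym,Symphytum officinale,Boraginaceae,alternate,herbaceous,simple,reticulodromous,15,189
Udj,Ulmus davidiana var. japonica,Ulmaceae,alternate,woody,simple,craspedodromous,15,418
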